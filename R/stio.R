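#' Spot-level expression dataset
#'
#' Container for a spot-based spatial gene-expression sample (or several merged
#' samples): a sparse nonnegative-integer gene x spot count matrix, per-spot
#' array/pixel positions and per-spot metadata (sample, genotype, age, and any
#' further columns such as cluster or region labels).
#'
#' Pixel coordinates are 0-based with x increasing rightwards and y downwards,
#' matching image-array indexing (row = y). Gene identity is by symbol string,
#' case-sensitive.
#'
#' @param counts gene x spot matrix of nonnegative integers (coerced to sparse).
#'   Must carry unique rownames (genes) and colnames (spot barcodes).
#' @param positions data.frame with columns `barcode`, `in_tissue`,
#'   `array_row`, `array_col`, `y_px`, `x_px`; one row per spot, same order as
#'   the columns of `counts`.
#' @param meta data.frame with columns `barcode`, `sample`, `genotype`
#'   (`"WT"`/`"AD"`), `age` (`"3M"`/`"7M"`); one row per spot.
#' @return object of class `spot_dataset` with elements `counts`, `positions`,
#'   `meta`.
#' @export
spot_dataset <- function(counts, positions, meta) {
  counts <- as_csparse(counts)
  if (any(counts@x < 0)) stopf("counts must be nonnegative")
  if (any(counts@x != round(counts@x))) stopf("counts must be integers")
  if (is.null(rownames(counts)) || anyDuplicated(rownames(counts)))
    stopf("counts must have unique rownames (gene ids)")
  cn <- colnames(counts)
  if (is.null(cn) && ncol(counts) == 0) cn <- character(0)
  if (is.null(cn) || anyDuplicated(cn))
    stopf("counts must have unique colnames (spot ids)")
  need_pos <- c("barcode", "in_tissue", "array_row", "array_col", "y_px", "x_px")
  if (!all(need_pos %in% names(positions)))
    stopf("positions must have columns: %s", paste(need_pos, collapse = ", "))
  need_meta <- c("barcode", "sample", "genotype", "age")
  if (!all(need_meta %in% names(meta)))
    stopf("meta must have columns: %s", paste(need_meta, collapse = ", "))
  if (nrow(positions) != ncol(counts) || nrow(meta) != ncol(counts))
    stopf("positions (%d) and meta (%d) rows must match n spots (%d)",
          nrow(positions), nrow(meta), ncol(counts))
  if (!identical(as.character(positions$barcode), cn) ||
      !identical(as.character(meta$barcode), cn))
    stopf("positions/meta barcodes must match counts colnames in order")
  rownames(positions) <- NULL
  rownames(meta) <- NULL
  structure(list(counts = counts, positions = positions, meta = meta),
            class = "spot_dataset")
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d genes x %d spots, %d sample(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$meta$sample))))
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) dim(x$counts)

#' Subset a spot dataset by spots
#'
#' @param x a `spot_dataset`
#' @param spots logical or integer index over spots
#' @return a `spot_dataset` restricted to the selected spots
#' @export
subset_spots <- function(x, spots) {
  spot_dataset(x$counts[, spots, drop = FALSE],
               x$positions[spots, , drop = FALSE],
               x$meta[spots, , drop = FALSE])
}

#' Write / read a dataset as a 10x-style MatrixMarket triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`, a tissue-positions CSV
#' (`tissue_positions.csv`, columns in 10x order: barcode, in_tissue,
#' array_row, array_col, y_px, x_px) and a `spot_meta.csv` with the sample /
#' genotype / age labels. `read_mtx_triplet(write_mtx_triplet(d))` reproduces
#' counts, ids and positions exactly (integer counts bit-exact, float positions
#' via full-precision decimal text).
#'
#' @param dataset a `spot_dataset`
#' @param dir directory to write to (created if missing)
#' @return `write_mtx_triplet` returns `dir` invisibly; `read_mtx_triplet`
#'   returns a `spot_dataset`.
#' @export
write_mtx_triplet <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(dataset$counts, file.path(dir, "matrix.mtx"))
  feats <- data.frame(id = rownames(dataset$counts),
                      name = rownames(dataset$counts),
                      type = "Gene Expression")
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(dataset$counts), file.path(dir, "barcodes.tsv"))
  pos <- dataset$positions
  pos$y_px <- format(pos$y_px, digits = 17, trim = TRUE, scientific = FALSE)
  pos$x_px <- format(pos$x_px, digits = 17, trim = TRUE, scientific = FALSE)
  utils::write.csv(pos, file.path(dir, "tissue_positions.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(dataset$meta, file.path(dir, "spot_meta.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_mtx_triplet
#' @export
read_mtx_triplet <- function(dir) {
  mtx <- as_csparse(Matrix::readMM(file.path(dir, "matrix.mtx")))
  feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                             header = FALSE, colClasses = "character")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  if (nrow(feats) != nrow(mtx))
    stopf("features.tsv has %d rows but matrix.mtx declares %d rows",
          nrow(feats), nrow(mtx))
  if (length(barcodes) != ncol(mtx))
    stopf("barcodes.tsv has %d rows but matrix.mtx declares %d columns",
          length(barcodes), ncol(mtx))
  rownames(mtx) <- feats[[1]]
  colnames(mtx) <- barcodes
  pos <- utils::read.csv(file.path(dir, "tissue_positions.csv"),
                         colClasses = c(barcode = "character"))
  meta_path <- file.path(dir, "spot_meta.csv")
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, colClasses = c(barcode = "character"))
  } else {
    meta <- data.frame(barcode = barcodes, sample = "sample1",
                       genotype = "WT", age = "3M")
  }
  pos <- pos[match(barcodes, pos$barcode), , drop = FALSE]
  meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
  spot_dataset(mtx, pos, meta)
}

#' Read gene sets in GMT format
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a set
#' are deduplicated with a warning; duplicate set names are an error.
#'
#' @param path path to a `.gmt` file
#' @return named list of character vectors (set name -> gene symbols)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stopf("empty GMT file: %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad))
    stopf("GMT line %d has %d field(s); need at least 3 (name, description, gene)",
          which(bad)[1], lengths(parts)[which(bad)[1]])
  nm <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stopf("duplicate gene-set name: %s", nm[duplicated(nm)][1])
  sets <- lapply(parts, function(p) p[-(1:2)])
  dups <- vapply(sets, anyDuplicated, integer(1)) > 0
  if (any(dups))
    warnf("duplicate genes within set(s) %s; deduplicated",
          paste(nm[dups], collapse = ", "))
  sets <- lapply(sets, unique)
  names(sets) <- nm
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors
#' @param path output path
#' @param description per-set description (recycled)
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- mapply(function(nm, gg, d) paste(c(nm, d, gg), collapse = "\t"),
                  names(sets), sets, rep_len(description, length(sets)))
  writeLines(lines, path)
  invisible(path)
}

#' Merge several samples into one dataset
#'
#' Takes the union of the gene universes (zero-filling genes absent from a
#' sample) and prefixes spot barcodes with the sample name. Metadata is
#' carried over; the `sample` column is set from `names(datasets)` when given.
#'
#' @param datasets list of `spot_dataset` objects
#' @return a merged `spot_dataset` with `sum(n spots)` spots
#' @export
merge_samples <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  if (length(datasets) == 1) return(datasets[[1]])
  nms <- names(datasets) %||% vapply(datasets, function(d) d$meta$sample[1], "")
  genes <- Reduce(union, lapply(datasets, function(d) rownames(d$counts)))
  parts <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    m <- Matrix::Matrix(0, length(genes), ncol(d$counts), sparse = TRUE,
                        dimnames = list(genes, NULL))
    m[rownames(d$counts), ] <- d$counts
    colnames(m) <- paste(nms[i], colnames(d$counts), sep = "_")
    m
  })
  counts <- do.call(cbind, parts)
  if (anyDuplicated(colnames(counts)))
    stopf("spot ids collide after prefixing with sample names")
  pos <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    p <- datasets[[i]]$positions
    p$barcode <- paste(nms[i], p$barcode, sep = "_")
    p
  }))
  meta <- do.call(rbind, lapply(seq_along(datasets), function(i) {
    m <- datasets[[i]]$meta
    m$barcode <- paste(nms[i], m$barcode, sep = "_")
    m$sample <- nms[i]
    m
  }))
  spot_dataset(as_csparse(counts), pos, meta)
}
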