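#' Spectral-count matrix with derived abundances
#'
#' The central container of the package: a proteins x experiments matrix of
#' raw spectral counts (SPC) together with per-protein molecular weights.
#' The derived abundance matrix `q = spc / mw` normalises each protein's
#' counts by the molecular weight of its largest isoform, approximately
#' accounting for the number of peptides a protein is expected to yield
#' (the same idea as NSAF, but not rescaled per experiment).
#'
#' @param spc numeric matrix of non-negative integer spectral counts with
#'   unique row names (protein identifiers) and unique column names
#'   (experiment identifiers).
#' @param mw named numeric vector of molecular weights, one per protein.
#'   Must cover every row of `spc`; must be positive for every protein with
#'   a nonzero count. One consistent unit (default kDa) is required across
#'   all proteins because the pair scores compare abundances across proteins.
#' @param mw_unit unit label recorded in the object metadata.
#'
#' @return An object of class `spc_matrix`: a list with elements `spc`
#'   (integer matrix), `q` (abundance matrix), `mw` (named vector) and
#'   `mw_unit`.
#' @export
spc_matrix <- function(spc, mw, mw_unit = "kDa") {
  if (!is.matrix(spc)) spc <- as.matrix(spc)
  pid <- rownames(spc)
  eid <- colnames(spc)
  if (is.null(pid) || anyDuplicated(pid))
    stop_usage("protein identifiers (row names) must be present and unique")
  if (is.null(eid) || anyDuplicated(eid))
    stop_usage("experiment identifiers (column names) must be present and unique")
  if (!is.numeric(spc) || anyNA(spc))
    stop_usage("spectral counts must be numeric and non-missing")
  if (any(spc < 0)) {
    bad <- which(spc < 0, arr.ind = TRUE)[1, ]
    stop_usage("negative spectral count at protein '", pid[bad[1]],
               "', experiment '", eid[bad[2]], "'")
  }
  if (any(spc != round(spc))) {
    bad <- which(spc != round(spc), arr.ind = TRUE)[1, ]
    stop_usage("non-integer spectral count at protein '", pid[bad[1]],
               "', experiment '", eid[bad[2]],
               "' (fractional counts are not supported)")
  }
  missing_mw <- setdiff(pid, names(mw))
  if (length(missing_mw))
    stop_usage("missing molecular weight for: ",
               paste(missing_mw, collapse = ", "))
  mw <- mw[pid]
  nonzero <- rowSums(spc) > 0
  bad_mw <- pid[nonzero & (is.na(mw) | mw <= 0)]
  if (length(bad_mw))
    stop_usage("non-positive molecular weight for proteins with counts: ",
               paste(bad_mw, collapse = ", "))
  storage.mode(spc) <- "integer"
  q <- spc / mw  # recycles by row
  q[is.na(q)] <- 0
  structure(list(spc = spc, q = q, mw = mw, mw_unit = mw_unit),
            class = "spc_matrix")
}

#' @export
print.spc_matrix <- function(x, ...) {
  cat(sprintf("spc_matrix: %d proteins x %d experiments (MW in %s)\n",
              nrow(x$spc), ncol(x$spc), x$mw_unit))
  cat(sprintf("  total counts: %d; nonzero cells: %d\n",
              sum(x$spc), sum(x$spc > 0)))
  invisible(x)
}

#' @rdname spc_matrix
#' @param x an `spc_matrix`.
#' @export
protein_ids <- function(x) rownames(x$spc)

#' @rdname spc_matrix
#' @export
experiment_ids <- function(x) colnames(x$spc)

#' Per-experiment metadata and identified-protein sets
#'
#' Pairs each experiment (column of an [spc_matrix]) with its bait, antibody,
#' cell line and condition, and with the set of proteins identified in it
#' (those with SPC > 0). The protein sets are derived from the matrix, so
#' they are consistent with it by construction.
#'
#' @param matrix an [spc_matrix].
#' @param bait,antibody,cell_line,condition optional character vectors, one
#'   entry per experiment (recycled if length 1).
#' @return An object of class `experiment_table`: list with `info`
#'   (data frame of metadata) and `protein_sets` (named list of character
#'   vectors).
#' @export
experiment_table <- function(matrix, bait = NA_character_,
                             antibody = NA_character_,
                             cell_line = NA_character_,
                             condition = NA_character_) {
  stopifnot(inherits(matrix, "spc_matrix"))
  eid <- experiment_ids(matrix)
  m <- length(eid)
  rec <- function(x) {
    if (length(x) == 1L) rep(as.character(x), m)
    else if (length(x) == m) as.character(x)
    else stop_usage("metadata vectors must have length 1 or n_experiments")
  }
  info <- data.frame(experiment = eid, bait = rec(bait),
                     antibody = rec(antibody), cell_line = rec(cell_line),
                     condition = rec(condition), stringsAsFactors = FALSE)
  sets <- lapply(seq_len(m), function(j)
    rownames(matrix$spc)[matrix$spc[, j] > 0])
  names(sets) <- eid
  structure(list(info = info, protein_sets = sets),
            class = "experiment_table")
}

#' @export
print.experiment_table <- function(x, ...) {
  sz <- lengths(x$protein_sets)
  cat(sprintf("experiment_table: %d experiments, list sizes %d-%d (median %d)\n",
              nrow(x$info), min(sz), max(sz), as.integer(stats::median(sz))))
  invisible(x)
}

#' Read a spectral-count matrix from delimited text
#'
#' The canonical interchange format is a TSV/CSV table whose first column
#' holds protein identifiers and remaining columns hold per-experiment
#' spectral counts, plus a two-column table mapping protein identifier to
#' molecular weight. An optional two-column identifier map (from, to) is
#' applied to protein identifiers at load time.
#'
#' @param path path to the count table.
#' @param mw_path path to the molecular-weight table (columns: protein, mw).
#' @param id_map optional data frame with columns `from`, `to`, applied to
#'   protein identifiers before matching molecular weights.
#' @param sep field separator; `"\t"` (default) or `","`.
#' @param mw_unit unit label recorded in the result.
#' @return An [spc_matrix].
#' @export
read_spc_matrix <- function(path, mw_path, id_map = NULL, sep = "\t",
                            mw_unit = "kDa") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA)
  if (ncol(tab) < 2) stop_usage("count table needs >= 1 experiment column")
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                  dimnames = dimnames(vals)))
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad)) {
      stop_usage("non-numeric spectral count at protein '", ids[bad[1, 1]],
                 "', experiment '", colnames(vals)[bad[1, 2]], "'")
    }
    vals <- num
  }
  rownames(vals) <- ids
  if (!is.null(id_map)) {
    stopifnot(all(c("from", "to") %in% names(id_map)))
    hit <- match(rownames(vals), id_map$from)
    rownames(vals)[!is.na(hit)] <- id_map$to[hit[!is.na(hit)]]
  }
  mwtab <- utils::read.table(mw_path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  mw <- stats::setNames(as.numeric(mwtab[[2]]), as.character(mwtab[[1]]))
  spc_matrix(vals, mw, mw_unit = mw_unit)
}

#' Write a spectral-count matrix (and its molecular weights) to TSV
#'
#' Inverse of [read_spc_matrix()]: `read_spc_matrix(path, mw_path)` on the
#' written files reproduces the object field-for-field.
#'
#' @param x an [spc_matrix].
#' @param path,mw_path output paths for the count and MW tables.
#' @export
write_spc_matrix <- function(x, path, mw_path) {
  stopifnot(inherits(x, "spc_matrix"))
  tab <- data.frame(protein = rownames(x$spc), x$spc,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mwtab <- data.frame(protein = names(x$mw), mw = unname(x$mw))
  utils::write.table(mwtab, mw_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
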