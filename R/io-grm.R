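#' Write a GRM in the GCTA binary convention
#'
#' Three files: `<prefix>.grm.bin` with the lower triangle (including the
#' diagonal) of the relationship matrix in row order as single-precision
#' floats, `<prefix>.grm.N.bin` with the per-pair non-missing SNP counts
#' in the same order and precision, and `<prefix>.grm.id` with family and
#' individual ids, tab-delimited.
#'
#' @param grm A `grm` object from [compute_grm()].
#' @param prefix Output path prefix.
#' @param families Optional family ids aligned with `grm$ids`; defaults to
#'   the individual ids.
#' @return Invisibly, the three paths.
#' @export
write_grm_bin <- function(grm, prefix, families = NULL) {
  stopifnot(inherits(grm, "grm"))
  n <- length(grm$ids)
  # GCTA order: pair (j,k) for j = 1..n, k = 1..j
  idx <- which(lower.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  vals <- grm$A[idx]
  cnts <- grm$N[idx]
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(as.numeric(vals), con, size = 4)
  close(con)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(as.numeric(cnts), con, size = 4)
  close(con)
  ids <- data.frame(family = families %||% grm$ids, id = grm$ids)
  write.table(ids, paste0(prefix, ".grm.id"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(paste0(prefix, c(".grm.bin", ".grm.N.bin", ".grm.id")))
}

#' Read a GCTA binary GRM
#'
#' @param prefix Path prefix of the .grm.bin/.grm.N.bin/.grm.id triplet.
#' @return A `grm` object (with `m` set to the maximum pair count).
#' @export
read_grm_bin <- function(prefix) {
  ids <- read.table(paste0(prefix, ".grm.id"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(ids)
  npair <- n * (n + 1) / 2
  vals <- readBin(paste0(prefix, ".grm.bin"), "numeric", n = npair, size = 4)
  cnts <- readBin(paste0(prefix, ".grm.N.bin"), "numeric", n = npair, size = 4)
  if (length(vals) != npair) stop("truncated .grm.bin")
  A <- matrix(0, n, n, dimnames = list(ids[[2]], ids[[2]]))
  N <- A
  idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  A[idx] <- vals
  N[idx] <- cnts
  A <- A + t(A) - diag(diag(A))
  N <- N + t(N) - diag(diag(N))
  structure(list(A = A, N = N, ids = ids[[2]], m = max(N)), class = "grm")
}

#' Write a GRM as plain text
#'
#' Tab-delimited long format: `id1`, `id2`, `n_snps`, `value`, one row per
#' lower-triangle pair including the diagonal.
#' @param grm A `grm` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_grm_text <- function(grm, path) {
  n <- length(grm$ids)
  idx <- which(lower.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  out <- data.frame(id1 = grm$ids[idx[, 1]], id2 = grm$ids[idx[, 2]],
                    n_snps = grm$N[idx], value = grm$A[idx])
  write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
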