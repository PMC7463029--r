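#' Pedigree kinship matrix
#'
#' Computes kinship coefficients by the standard recursion over a
#' topologically ordered pedigree: founders are mutually unrelated with
#' self-kinship 1/2; for a non-founder j with parents f and m,
#' `phi(j,j) = (1 + phi(f,m)) / 2` and `phi(j,k) = (phi(f,k) + phi(m,k)) / 2`
#' for any k that is not a descendant of j. A missing parent is treated as
#' an unknown, unrelated founder. `2 * Phi` is the expected additive
#' relationship matrix used as the polygenic covariance structure.
#'
#' @param ped A `pedigree` data frame (`id`, `father`, `mother`; families
#'   are assumed mutually unrelated).
#' @return Symmetric kinship matrix with `ped$id` dimnames; class
#'   `kinship` on top of `matrix`.
#' @export
#' @examples
#' ped <- simulate_pedigrees(1, seed = 1)
#' kinship_matrix(ped)[1:4, 1:4]
kinship_matrix <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  ord <- topo_order(ped$id, ped$father, ped$mother)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  done <- integer(0)
  for (j in ord) {
    fa <- ped$father[j]
    mo <- ped$mother[j]
    fi <- if (is.na(fa)) NA_integer_ else idx[[fa]]
    mi <- if (is.na(mo)) NA_integer_ else idx[[mo]]
    if (is.na(fi) && is.na(mi)) {
      phi[j, j] <- 0.5
    } else {
      pf <- if (is.na(fi)) rep(0, length(done)) else phi[fi, done]
      pm <- if (is.na(mi)) rep(0, length(done)) else phi[mi, done]
      if (length(done)) {
        phi[j, done] <- 0.5 * (pf + pm)
        phi[done, j] <- phi[j, done]
      }
      phi_fm <- if (is.na(fi) || is.na(mi)) 0 else phi[fi, mi]
      phi[j, j] <- 0.5 * (1 + phi_fm)
    }
    done <- c(done, j)
  }
  class(phi) <- c("kinship", "matrix", "array")
  phi
}
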