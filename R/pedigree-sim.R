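#' Family-structure configuration for the synthetic cohort
#'
#' Describes how extended families are assembled: an optional grandparent
#' couple, a parent couple, and a sibship whose size is drawn from a
#' discrete distribution with a configurable minimum (the recruitment rule
#' required sibships of three or more). Spouses marrying into a family are
#' unrelated founders. The phenotyping probabilities are calibrated so that
#' the default 108-family cohort carries roughly 340 phenotyped members.
#'
#' @param min_sibship Minimum number of siblings per family (default 3).
#' @param sibship_sizes Integer vector of possible sibship sizes. Defaults
#'   to `min_sibship + 0:6`.
#' @param sibship_probs Probabilities for `sibship_sizes`; must sum to 1.
#'   Defaults to a Poisson(0.7) offset above the minimum.
#' @param grandparent_prob Probability that a grandparent couple (parents of
#'   one member of the parent couple) is included in the family.
#' @param p_phenotyped Named numeric vector with elements `grandparent`,
#'   `parent` and `sib`: the probability that a member of each role attended
#'   imaging. The proband sib is always phenotyped.
#' @param genotyped_rate Probability that an individual has usable
#'   genotypes (about 10\% of the imaged cohort was not genotyped).
#' @param age_range Permitted age range in years.
#'
#' @return A list of class `cohort_structure`.
#' @export
cohort_structure <- function(min_sibship = 3,
                             sibship_sizes = NULL,
                             sibship_probs = NULL,
                             grandparent_prob = 0.3,
                             p_phenotyped = c(grandparent = 0.10,
                                              parent = 0.30,
                                              sib = 0.55),
                             genotyped_rate = 0.90,
                             age_range = c(19, 73)) {
  if (is.null(sibship_sizes)) {
    sibship_sizes <- min_sibship + 0:6
    sibship_probs <- stats::dpois(0:6, 0.7)
    sibship_probs <- sibship_probs / sum(sibship_probs)
  }
  if (is.null(sibship_probs) || length(sibship_probs) != length(sibship_sizes)) {
    stop("sibship_probs must accompany sibship_sizes, one probability per size")
  }
  if (abs(sum(sibship_probs) - 1) > 1e-6) {
    stop("invalid sibship distribution: probabilities must sum to 1")
  }
  if (any(sibship_sizes < 1)) stop("sibship sizes must be positive")
  stopifnot(all(c("grandparent", "parent", "sib") %in% names(p_phenotyped)))
  structure(list(min_sibship = min_sibship,
                 sibship_sizes = as.integer(sibship_sizes),
                 sibship_probs = sibship_probs,
                 grandparent_prob = grandparent_prob,
                 p_phenotyped = p_phenotyped,
                 genotyped_rate = genotyped_rate,
                 age_range = age_range),
            class = "cohort_structure")
}

#' Simulate extended-family pedigrees
#'
#' Builds `n_families` independent families under a three-generation design:
#' an optional founder grandparent couple, a parent couple (one parent a
#' child of the grandparents when present, the spouse an unrelated founder),
#' and a sibship of configurable size. One sibling per family is marked as
#' the proband (the hypertensive index case through whom the family was
#' ascertained) and is always phenotyped; other members are phenotyped with
#' role-specific probabilities.
#'
#' @param n_families Number of families to generate (>= 1).
#' @param structure A [cohort_structure()] configuration.
#' @param seed Integer seed; the generator is a pure function of
#'   `(structure, seed)`.
#'
#' @return A `data.frame` of class `pedigree` with columns `family`, `id`,
#'   `father`, `mother`, `sex` ("male"/"female"), `founder`, `generation`
#'   (0 = grandparents), `proband`, `phenotyped`, `genotyped`.
#' @export
#' @examples
#' ped <- simulate_pedigrees(2, seed = 1)
#' table(ped$family)
simulate_pedigrees <- function(n_families, structure = cohort_structure(),
                               seed = NULL) {
  if (n_families < 1) stop("n_families must be >= 1")
  if (!inherits(structure, "cohort_structure")) {
    structure <- do.call(cohort_structure, structure)
  }
  with_seed(seed, {
    fams <- lapply(seq_len(n_families), function(f) {
      simulate_one_family(sprintf("F%03d", f), structure)
    })
    ped <- data.frame(
      family = unlist(lapply(fams, `[[`, "family")),
      id = unlist(lapply(fams, `[[`, "id")),
      father = unlist(lapply(fams, `[[`, "father")),
      mother = unlist(lapply(fams, `[[`, "mother")),
      sex = unlist(lapply(fams, `[[`, "sex")),
      founder = unlist(lapply(fams, `[[`, "founder")),
      generation = unlist(lapply(fams, `[[`, "generation")),
      proband = unlist(lapply(fams, `[[`, "proband")),
      phenotyped = unlist(lapply(fams, `[[`, "phenotyped")),
      genotyped = unlist(lapply(fams, `[[`, "genotyped")),
      stringsAsFactors = FALSE)
    class(ped) <- c("pedigree", "data.frame")
    validate_pedigree(ped)
    ped
  })
}

simulate_one_family <- function(fid, cfg) {
  pph <- cfg$p_phenotyped
  has_gp <- runif(1) < cfg$grandparent_prob
  n_sibs <- sample(length(cfg$sibship_sizes), 1L, prob = cfg$sibship_probs)
  n_sibs <- cfg$sibship_sizes[n_sibs]
  n <- (if (has_gp) 2L else 0L) + 2L + n_sibs
  id <- sprintf("%s_%02d", fid, seq_len(n))
  father <- rep(NA_character_, n)
  mother <- rep(NA_character_, n)
  sex <- character(n)
  founder <- rep(TRUE, n)
  gen <- integer(n)
  proband <- rep(FALSE, n)
  ph <- logical(n)
  k <- 0L
  gpf <- gpm <- NA_character_
  if (has_gp) {
    gpf <- id[1L]; gpm <- id[2L]
    sex[1:2] <- c("male", "female")
    gen[1:2] <- 0L
    ph[1:2] <- runif(2) < pph[["grandparent"]]
    k <- 2L
  }
  # parent couple: when grandparents exist, one parent descends from them
  pa <- id[k + 1L]; ma <- id[k + 2L]
  sex[k + 1:2] <- c("male", "female")
  gen[k + 1:2] <- 1L
  ph[k + 1:2] <- runif(2) < pph[["parent"]]
  if (has_gp) {
    lineal <- if (runif(1) < 0.5) k + 1L else k + 2L
    father[lineal] <- gpf
    mother[lineal] <- gpm
    founder[lineal] <- FALSE
  }
  k <- k + 2L
  sib_idx <- k + seq_len(n_sibs)
  father[sib_idx] <- pa
  mother[sib_idx] <- ma
  sex[sib_idx] <- ifelse(runif(n_sibs) < 0.49, "male", "female")
  founder[sib_idx] <- FALSE
  gen[sib_idx] <- 2L
  proband[sib_idx[1L]] <- TRUE
  ph[sib_idx] <- runif(n_sibs) < pph[["sib"]]
  ph[sib_idx[1L]] <- TRUE
  list(family = rep(fid, n), id = id, father = father, mother = mother,
       sex = sex, founder = founder, generation = gen, proband = proband,
       phenotyped = ph, genotyped = runif(n) < cfg$genotyped_rate)
}

#' Validate a pedigree
#'
#' Checks structural invariants: every referenced parent exists, founders
#' have no parents, non-founders have at least one parent recorded, the
#' parent graph is acyclic, and each family has exactly one proband.
#'
#' @param ped A `pedigree` data frame.
#' @return Invisibly, `ped`; errors describe the violated invariant.
#' @export
validate_pedigree <- function(ped) {
  req <- c("family", "id", "father", "mother", "sex", "founder",
           "proband", "phenotyped")
  missing_cols <- setdiff(req, names(ped))
  if (length(missing_cols)) {
    stop("pedigree lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(ped$id)) stop("duplicate individual ids")
  founder_with_parent <- ped$founder & (!is.na(ped$father) | !is.na(ped$mother))
  if (any(founder_with_parent)) stop("founders must have no parents")
  topo_order(ped$id, ped$father, ped$mother)  # errors on cycles/missing parents
  pro <- tapply(ped$proband, ped$family, sum)
  if (any(pro != 1L)) stop("each family must contain exactly one proband")
  invisible(ped)
}
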