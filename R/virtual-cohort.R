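#' @title Virtual cohorts
#' @description Expand small healthy-control input sets to patient-group
#'   sizes: SMOTE augmentation of cortisol profiles, hypnogram resampling,
#'   and assembly of per-virtual-subject forcing inputs.
#' @name virtual_cohort
NULL

#' SMOTE augmentation of cortisol profiles
#'
#' Each synthetic profile is `x + u * (x_nn - x)` for a uniformly drawn
#' donor profile `x`, one of its `k` nearest neighbours `x_nn` (Euclidean
#' distance on the 145-dimensional concentration vectors), and
#' `u ~ Uniform(0, 1)`. Interpolation is applied to whole profiles (one
#' neighbour draw per synthetic profile), so pulse structure within a
#' profile is preserved, and non-negativity follows from convexity.
#'
#' @param profiles list of `cort_profile` (>= 2).
#' @param n_synthetic number of synthetic profiles to generate.
#' @param k neighbourhood size (default 3; must be `< length(profiles)`).
#' @param seed integer seed.
#' @return List of `n_synthetic` synthetic `cort_profile` objects with ids
#'   `smote_<i>`.
#' @export
smote_profiles <- function(profiles, n_synthetic, k = 3, seed = NULL) {
  n <- length(profiles)
  if (k >= n) stopf("k (%d) must be smaller than the number of profiles (%d)",
                    k, n)
  if (n_synthetic < 0) stopf("n_synthetic must be non-negative")
  X <- t(vapply(profiles, `[[`, numeric(145), "concentrations"))
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  nn_idx <- t(apply(D, 1, function(d) order(d)[seq_len(k)]))
  with_seed(seed, {
    lapply(seq_len(n_synthetic), function(i) {
      b <- sample.int(n, 1)
      nn <- nn_idx[b, sample.int(k, 1)]
      u <- runif(1)
      cort_profile(X[b, ] + u * (X[nn, ] - X[b, ]),
                   subject_id = sprintf("smote_%03d", i))
    })
  })
}

#' Resample a sleep cohort to a target size
#'
#' Upsampling adds `target_n - n` *distinct* donors (duplicated once each)
#' to the full original cohort, so no subject appears more than twice;
#' downsampling takes a simple random subset without replacement.
#'
#' @param hypnograms list of `hypnogram`.
#' @param target_n requested cohort size (at most `2 * length(hypnograms)`).
#' @param seed integer seed.
#' @return List of `target_n` hypnograms.
#' @export
resample_sleep_cohort <- function(hypnograms, target_n, seed = NULL) {
  n <- length(hypnograms)
  if (target_n > 2 * n)
    stopf("target size %d exceeds twice the cohort size (%d)", target_n, 2 * n)
  with_seed(seed, {
    if (target_n > n) {
      extra <- sample.int(n, target_n - n)  # without repetition
      c(hypnograms, hypnograms[extra])
    } else if (target_n < n) {
      hypnograms[sample.int(n, target_n)]
    } else hypnograms
  })
}

#' Assemble a virtual cohort
#'
#' Expands the donor hypnogram and cortisol sets to the patient-group size
#' (66 for group 1, 41 for group 2 by default), pairs each member with one
#' hypnogram and one cortisol profile uniformly at random, samples a
#' per-member cortisol action delay from N(`phi_mean_min`, `phi_sd_min`)
#' truncated at zero, and derives per-member child seeds from the master
#' seed.
#'
#' @param group_id 1 or 2.
#' @param hypnograms donor hypnograms.
#' @param cort_profiles donor cortisol profiles.
#' @param params a `forcing_params`.
#' @param target_n cohort size (defaults to 66 / 41 by group).
#' @param smote_k SMOTE neighbourhood size.
#' @param seed master seed.
#' @return An object of class `virtual_cohort` with `members`, each a list
#'   of `hypnogram`, `cort`, `phi_min`, `seed`, `cort_synthetic`.
#' @export
assemble_cohort <- function(group_id, hypnograms, cort_profiles,
                            params = forcing_params(), target_n = NULL,
                            smote_k = 3, seed = NULL) {
  if (!group_id %in% 1:2) stopf("group_id must be 1 or 2")
  target_n <- target_n %||% c(66L, 41L)[group_id]
  with_seed(seed, {
    hyps <- resample_sleep_cohort(hypnograms, target_n)
    n_syn <- target_n - length(cort_profiles)
    if (n_syn >= 0) {
      synth <- smote_profiles(cort_profiles, n_syn, k = smote_k)
      profs <- c(cort_profiles, synth)
      synthetic <- c(rep(FALSE, length(cort_profiles)), rep(TRUE, n_syn))
    } else {
      # scaled-down cohorts: a random subset of donors, no augmentation
      profs <- cort_profiles[sample.int(length(cort_profiles), target_n)]
      synthetic <- rep(FALSE, target_n)
    }
    ord <- sample.int(target_n)
    phis <- vapply(seq_len(target_n), function(i)
      rtruncnorm0(params$phi_mean_min, params$phi_sd_min), 0)
    seeds <- child_seeds(target_n)
    members <- lapply(seq_len(target_n), function(i) {
      list(hypnogram = hyps[[i]], cort = profs[[ord[i]]],
           cort_synthetic = synthetic[ord[i]],
           phi_min = phis[i], seed = seeds[i])
    })
    structure(list(group_id = group_id, members = members,
                   size = target_n, params = params, seed = seed),
              class = "virtual_cohort")
  })
}

#' Write a virtual-cohort manifest
#'
#' JSON record of the cohort composition: per member, the hypnogram and
#' cortisol input identifiers, whether the profile is a SMOTE surrogate,
#' the sampled action delay and the child simulation seed, plus the master
#' seed the cohort is reproducible from.
#'
#' @param cohort a `virtual_cohort`.
#' @param path output path (`.json`).
#' @return Invisibly, the path.
#' @export
write_cohort_manifest <- function(cohort, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stopf("writing manifests requires the jsonlite package")
  manifest <- list(
    group_id = cohort$group_id,
    size = cohort$size,
    master_seed = cohort$seed,
    params = unclass(cohort$params),
    members = lapply(cohort$members, function(m)
      list(hypnogram = m$hypnogram$subject_id,
           cort_profile = m$cort$subject_id,
           cort_synthetic = m$cort_synthetic,
           phi_min = m$phi_min,
           seed = m$seed))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.virtual_cohort <- function(x, ...) {
  n_syn <- sum(vapply(x$members, `[[`, TRUE, "cort_synthetic"))
  cat(sprintf("<virtual_cohort> group %d: %d members (%d synthetic cortisol profiles)\n",
              x$group_id, x$size, n_syn))
  invisible(x)
}
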