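#' Derive combination energy terms per MM/PBSA snapshot
#'
#' Adds the standard derived columns to a per-snapshot energy-component
#' table: the molecular-mechanics energy `e_mm = e_vdw + e_ele`, the total
#' solvation term `g_solv = g_solv_polar + g_solv_nonpolar`, and the two
#' diagnostic combinations `polar_plus_ele` and `nonpolar_plus_vdw` that
#' separate the electrostatic from the hydrophobic driving force.
#'
#' @param table Data frame with numeric columns `e_vdw`, `e_ele`,
#'   `g_solv_polar`, `g_solv_nonpolar` (kcal/mol), one row per snapshot.
#' @return The input tibble with columns `e_mm`, `g_solv`,
#'   `polar_plus_ele`, `nonpolar_plus_vdw` appended.
#' @examples
#' derive_terms(tibble::tibble(
#'   e_vdw = -35.12, e_ele = -17.05, g_solv_polar = 29.69, g_solv_nonpolar = -5.51
#' ))
#' @export
derive_terms <- function(table) {
  check_columns(table, c("e_vdw", "e_ele", "g_solv_polar", "g_solv_nonpolar"),
                "energy-component table")
  if (nrow(table) < 1) hg_abort("Energy table has no rows.", "input")
  num <- c("e_vdw", "e_ele", "g_solv_polar", "g_solv_nonpolar")
  if (!all(vapply(table[num], is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(table[num])))) {
    hg_abort("Energy components must be finite numbers.", "input")
  }
  as_tibble(table) |>
    mutate(
      e_mm = .data$e_vdw + .data$e_ele,
      g_solv = .data$g_solv_polar + .data$g_solv_nonpolar,
      polar_plus_ele = .data$g_solv_polar + .data$e_ele,
      nonpolar_plus_vdw = .data$g_solv_nonpolar + .data$e_vdw
    )
}

#' Summarise MM/PBSA energy components across replicate simulations
#'
#' Aggregates per-snapshot energy components into the standard binding
#' summary: per-replicate means first, then the cross-replicate mean and
#' SEM (sd/sqrt(n)) of every term, the entropy term, and the assembled
#' binding free energy `g_bind = e_mm + g_solv - t_delta_s`. The entropy
#' contribution enters once per replicate (one `t_delta_s` value each), as
#' normal-mode/quasi-harmonic entropies are not per-snapshot quantities.
#'
#' @param replicates Data frame of per-snapshot components with a
#'   `replicate` column (see [derive_terms()] for the energy columns), or a
#'   list of per-replicate data frames.
#' @param entropy Data frame with columns `replicate` and `t_delta_s`
#'   (kcal/mol), one row per replicate, or a numeric vector in replicate
#'   order.
#' @param g_exp Optional experimental binding free energy (kcal/mol) to
#'   report the deviation against.
#' @param sem_mode `"replicate"` (default): SEM of the per-replicate means,
#'   n = number of replicates. `"snapshot"`: SEM across all pooled
#'   snapshots (entropy SEM still across replicates).
#'
#' @return An object of class `hg_mmpbsa`: list with `terms` (tibble of
#'   term, mean, sem), `g_bind`, `g_bind_sem`, `g_exp`, `delta_vs_exp`,
#'   `n_replicates`, `n_snapshots`, `sem_mode`. Has a [tidy()] method
#'   returning the term table.
#' @export
summarize_mmpbsa <- function(replicates, entropy, g_exp = NULL,
                             sem_mode = c("replicate", "snapshot")) {
  sem_mode <- match.arg(sem_mode)
  if (is.data.frame(replicates)) {
    check_columns(replicates, "replicate", "energy-component table")
    replicates <- split(as_tibble(replicates), replicates$replicate)
  }
  n_rep <- length(replicates)
  if (n_rep < 1) hg_abort("Need at least one replicate.", "input")
  if (is.data.frame(entropy)) {
    check_columns(entropy, c("replicate", "t_delta_s"), "entropy table")
    entropy <- entropy$t_delta_s[order(entropy$replicate)]
  }
  if (length(entropy) != n_rep) {
    hg_abort(sprintf("Entropy terms (%d) must match replicate count (%d).",
                     length(entropy), n_rep), "input")
  }

  extended <- purrr::map(replicates, derive_terms)
  terms <- c("e_vdw", "e_ele", "e_mm", "g_solv_polar", "g_solv_nonpolar",
             "g_solv", "polar_plus_ele", "nonpolar_plus_vdw")
  rep_means <- purrr::map(extended, function(tb) colMeans(tb[terms]))
  rep_means <- do.call(rbind, rep_means) # n_rep x terms

  sem_of <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  term_mean <- colMeans(rep_means)
  term_sem <- if (sem_mode == "replicate") {
    apply(rep_means, 2, sem_of)
  } else {
    pooled <- bind_rows(extended)
    vapply(terms, function(tm) sem_of(pooled[[tm]]), numeric(1))
  }

  tds_mean <- mean(entropy)
  tds_sem <- sem_of(entropy)
  # per-replicate binding energy, then cross-replicate spread
  g_bind_rep <- rep_means[, "e_mm"] + rep_means[, "g_solv"] - entropy
  g_bind <- term_mean[["e_mm"]] + term_mean[["g_solv"]] - tds_mean
  g_bind_sem <- sem_of(g_bind_rep)

  term_tbl <- tibble(
    term = c(terms, "t_delta_s", "g_bind"),
    mean = c(unname(term_mean), tds_mean, g_bind),
    sem = c(unname(term_sem), tds_sem, g_bind_sem)
  )
  structure(
    list(
      terms = term_tbl,
      g_bind = g_bind,
      g_bind_sem = g_bind_sem,
      g_exp = g_exp,
      delta_vs_exp = if (is.null(g_exp)) NULL else g_bind - g_exp,
      n_replicates = n_rep,
      n_snapshots = sum(vapply(extended, nrow, integer(1))),
      sem_mode = sem_mode
    ),
    class = "hg_mmpbsa"
  )
}

#' @export
print.hg_mmpbsa <- function(x, ...) {
  cat(sprintf("MM/PBSA summary (%d replicates, %d snapshots, SEM over %ss)\n",
              x$n_replicates, x$n_snapshots, x$sem_mode))
  tb <- x$terms
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-18s %8.2f +/- %s kcal/mol\n", tb$term[i], tb$mean[i],
                ifelse(is.na(tb$sem[i]), "   NA", sprintf("%5.2f", tb$sem[i]))))
  }
  if (!is.null(x$g_exp)) {
    cat(sprintf("  vs experiment %.2f: deviation %+.2f kcal/mol\n",
                x$g_exp, x$delta_vs_exp))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hg_mmpbsa <- function(x, ...) x$terms

#' @exportS3Method generics::glance
glance.hg_mmpbsa <- function(x, ...) {
  tibble(
    g_bind = x$g_bind, g_bind_sem = x$g_bind_sem,
    g_exp = x$g_exp %||% NA_real_,
    delta_vs_exp = x$delta_vs_exp %||% NA_real_,
    n_replicates = x$n_replicates, n_snapshots = x$n_snapshots
  )
}

#' Deviation of the computed binding free energy from experiment
#'
#' @param summary An `hg_mmpbsa` from [summarize_mmpbsa()].
#' @param g_exp Experimental binding free energy (kcal/mol), e.g. from a
#'   Van't Hoff analysis of the same complex.
#' @return Signed difference `g_bind - g_exp` in kcal/mol.
#' @export
compare_experiment <- function(summary, g_exp) {
  check_number(g_exp, "g_exp")
  if (is.null(summary$g_bind)) hg_abort("Summary lacks `g_bind`.", "input")
  summary$g_bind - g_exp
}
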