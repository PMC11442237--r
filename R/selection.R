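#' Progressive exposure-control weights
#'
#' Blends a uniform random component with information so that early picks
#' are near-random and late picks near maximum-information: with `h` items
#' already administered out of `t`, the relative serial position is
#' \eqn{s = h/t}, a random value \eqn{R_i \sim U(0, H)} is drawn per
#' candidate (H = the maximum candidate information), and the selection
#' weight is \eqn{w_i = (1-s) R_i + s I_i}.
#'
#' Draws come from the ambient RNG (seed the session or study for
#' reproducibility); `draws` allows injecting fixed values, e.g. to stub
#' \eqn{R_i \equiv H/2} in tests or to disable the random component.
#'
#' @param candidate_infos Named numeric vector: item id -> information (the
#'   selection currency, usually RP-shifted information).
#' @param h Number of items already administered (0 <= h < t).
#' @param t Test length.
#' @param draws Optional fixed random values (recycled to the candidates).
#' @return An object of class `hat_progressive_draw` with fields `h`, `t`,
#'   `s`, `H`, `draws`, `weights`.
#' @export
progressive_weights <- function(candidate_infos, h, t, draws = NULL) {
  if (!length(candidate_infos))
    stop_hat("no candidates to weight", "hatcat_domain_error")
  if (h < 0 || h >= t)
    stop_hat("need 0 <= h < t", "hatcat_domain_error")
  s <- h / t
  H <- max(candidate_infos)
  n <- length(candidate_infos)
  R <- if (is.null(draws)) {
    if (H > 0) stats::runif(n, 0, H) else numeric(n)
  } else rep_len(draws, n)
  w <- (1 - s) * R + s * candidate_infos
  structure(list(h = h, t = t, s = s, H = H,
                 draws = stats::setNames(R, names(candidate_infos)),
                 weights = stats::setNames(w, names(candidate_infos))),
            class = "hat_progressive_draw")
}

#' Subpool ordering plan for item-position balancing
#'
#' Each domain's two clusters present the two IPE subpools in opposite
#' order: cluster 1 administers subpool-A items before subpool-B items,
#' cluster 2 the reverse. The first-ordered subpool's quota is half the
#' cluster's item budget, rounded up.
#'
#' @param cluster_length Items per cluster (t/2).
#' @param order1 Subpool order of a domain's first cluster.
#' @return List of per-cluster plans (`first`, `quota`).
#' @export
ipe_plan <- function(cluster_length, order1 = c("A", "B")) {
  q <- ceiling(cluster_length / 2)
  list(list(first = order1[1], quota = q),
       list(first = order1[2], quota = q))
}

#' IPE-eligible candidates
#'
#' While the cluster's first-ordered subpool has not met its quota of
#' administered items, only candidates from that subpool are eligible;
#' afterwards only the second subpool's.
#'
#' @param candidates Character vector of candidate item ids.
#' @param subpool Named character vector (item id -> "A"/"B") covering the
#'   candidates.
#' @param first First-ordered subpool of the current cluster.
#' @param n_first_done Items of the first subpool already administered in
#'   this cluster.
#' @param quota First subpool's quota in this cluster.
#' @return The eligible subset (possibly empty).
#' @export
ipe_eligible <- function(candidates, subpool, first, n_first_done, quota) {
  lab <- subpool[candidates]
  if (anyNA(lab))
    stop_hat("candidate(s) lack a subpool label",
             "hatcat_labeling_error")
  want <- if (n_first_done < quota) first else setdiff(c("A", "B"), first)
  candidates[lab == want]
}

#' Pick the next item from a solved shadow test
#'
#' Among eligible, unadministered shadow items, returns the one with the
#' maximal selection weight; ties break to the lexicographically smallest
#' item id. An administered item is never returned.
#'
#' @param shadow A [solve_shadow()] result.
#' @param administered Character vector of administered item ids.
#' @param weights Named weights (e.g. from [progressive_weights()]) for at
#'   least the unadministered shadow items.
#' @param eligible Optional id subset (e.g. from [ipe_eligible()]).
#' @return A single item id.
#' @export
pick_item <- function(shadow, administered, weights, eligible = NULL) {
  cand <- setdiff(shadow$selected_item_ids, administered)
  if (!is.null(eligible)) cand <- intersect(cand, eligible)
  if (!length(cand))
    stop_hat("no eligible unadministered item in the shadow test",
             "hatcat_selection_error")
  w <- weights[cand]
  best <- cand[w >= max(w) - 1e-12]
  sort(best)[1]
}

#' Spiraled assignment of complete link units
#'
#' Student j receives the units at positions j and j + 1 (1-based,
#' wrapping), guaranteeing every unit a minimum number of non-adaptive
#' administrations across students.
#'
#' @param units Ordered character vector of unit ids.
#' @param student_index 1-based student counter.
#' @return Character vector of two unit ids.
#' @examples
#' spiral_units(paste0("U", 1:5), 1)  # U1 U2
#' spiral_units(paste0("U", 1:5), 5)  # U5 U1
#' @export
spiral_units <- function(units, student_index) {
  S <- length(units)
  if (S < 2)
    stop_hat("spiraling needs at least two units", "hatcat_domain_error")
  i1 <- ((student_index - 1L) %% S) + 1L
  i2 <- (student_index %% S) + 1L
  c(units[i1], units[i2])
}
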