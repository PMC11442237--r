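#' Specification for synthetic pool generation
#'
#' Describes a unit-nested pool realistic enough to exercise the full
#' design: log-normal discriminations, normal difficulties, a share of
#' polytomous (GPCM) items, and categorical attributes sampled from given
#' frequencies. The per-domain helpers [reading_pool_spec()],
#' [mathematics_pool_spec()] and [science_pool_spec()] pre-fill attribute
#' frequencies that satisfy the shipped blueprints with headroom.
#'
#' @param n_units Number of units.
#' @param items_per_unit Integer range `c(min, max)` of unit sizes.
#' @param a_meanlog,a_sdlog Log-normal parameters of the discriminations.
#' @param b_mean,b_sd Normal parameters of the difficulties.
#' @param prop_polytomous Fraction of GPCM items.
#' @param n_categories Categories of polytomous items (default 3, i.e. two
#'   step parameters).
#' @param step_sd Spread of the GPCM step parameters around zero.
#' @param attribute_frequencies Named list: attribute -> named probability
#'   vector over categories (each must sum to 1).
#' @param margin Multiplicative headroom required over every blueprint
#'   lower bound (>= 1).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return An object of class `hat_poolgen_spec`.
#' @export
pool_gen_spec <- function(n_units, items_per_unit = c(3, 3),
                          a_meanlog = 0, a_sdlog = 0.3,
                          b_mean = 0, b_sd = 1,
                          prop_polytomous = 0.2, n_categories = 3,
                          step_sd = 0.5,
                          attribute_frequencies = list(),
                          margin = 1.5, seed = NULL) {
  if (margin < 1) stop_hat("margin must be >= 1", "hatcat_domain_error")
  if (prop_polytomous < 0 || prop_polytomous > 1)
    stop_hat("prop_polytomous must lie in [0, 1]", "hatcat_domain_error")
  for (att in names(attribute_frequencies)) {
    p <- attribute_frequencies[[att]]
    if (abs(sum(p) - 1) > 1e-8)
      stop_hat(paste0("frequencies for attribute '", att,
                      "' must sum to 1"), "hatcat_domain_error")
  }
  structure(list(n_units = n_units,
                 items_per_unit = as.integer(items_per_unit),
                 a_meanlog = a_meanlog, a_sdlog = a_sdlog,
                 b_mean = b_mean, b_sd = b_sd,
                 prop_polytomous = prop_polytomous,
                 n_categories = as.integer(n_categories),
                 step_sd = step_sd,
                 attribute_frequencies = attribute_frequencies,
                 margin = margin, seed = seed),
            class = "hat_poolgen_spec")
}

#' @rdname pool_gen_spec
#' @export
reading_pool_spec <- function(n_units = 40, seed = NULL, margin = 1.5, ...) {
  pool_gen_spec(
    n_units = n_units, items_per_unit = c(3, 3), margin = margin,
    seed = seed,
    attribute_frequencies = list(
      cognitive_process = c(Scan = 5, Represent = 5, Integrate_single = 5,
                            Integrate_multiple = 5, Reflect = 3.5,
                            Assess = 3.5, Corroborate = 4, Search = 4) / 35,
      coding = c(human = 1 / 3, machine = 2 / 3),
      text_type = c(single = 0.8, multiple = 0.2),
      trend = c(trend = 0.4, new = 0.6)),
    ...)
}

#' @rdname pool_gen_spec
#' @export
mathematics_pool_spec <- function(n_units = 30, seed = NULL, margin = 1.5,
                                  ...) {
  pool_gen_spec(
    n_units = n_units, items_per_unit = c(1, 4), margin = margin,
    seed = seed,
    attribute_frequencies = list(
      cognitive_process = c(Employ = 1, Formulate = 1, Interpret = 1) / 3,
      content = c(Change = 1, Space = 1, Quantity = 1, Uncertainty = 1) / 4,
      coding = c(human = 0.25, machine = 0.75)),
    ...)
}

#' @rdname pool_gen_spec
#' @export
science_pool_spec <- function(n_units = 36, seed = NULL, margin = 1.5, ...) {
  pool_gen_spec(
    n_units = n_units, items_per_unit = c(2, 5), margin = margin,
    seed = seed,
    attribute_frequencies = list(
      competency = c(Evaluate = 9, Explain = 16, Interpret = 12.5) / 37.5,
      knowledge = c(Content = 21.5, Epistemic = 6, Procedural = 9) / 36.5,
      system = c(Earth = 10, Living = 13, Physical = 13) / 36,
      coding = c(human = 10 / 36, machine = 26 / 36),
      trend_type = c(Standard = 0.72, Interactive = 0.21, New = 0.07)),
    ...)
}

#' Generate a synthetic unit-nested item pool
#'
#' Deterministic given `spec$seed` (the caller's RNG state is restored).
#' When a blueprint is supplied, the generated pool is required to hold at
#' least `margin` times every categorical lower bound; otherwise generation
#' aborts naming the binding constraint.
#'
#' @param spec A [pool_gen_spec()].
#' @param blueprint Optional [hat_blueprint()] to check headroom against.
#' @param domain Domain label of the resulting pool.
#' @return A [hat_pool()].
#' @export
generate_synthetic_pool <- function(spec, blueprint = NULL, domain = "GEN") {
  with_local_seed(spec$seed, {
    sizes <- if (spec$items_per_unit[1] == spec$items_per_unit[2])
      rep(spec$items_per_unit[1], spec$n_units)
    else sample(spec$items_per_unit[1]:spec$items_per_unit[2],
                spec$n_units, replace = TRUE)
    I <- sum(sizes)
    unit_ids <- sprintf("U%03d", seq_len(spec$n_units))
    items <- data.frame(
      item_id = sprintf("I%04d", seq_len(I)),
      unit_id = rep(unit_ids, sizes),
      stringsAsFactors = FALSE)
    items$model <- ifelse(stats::runif(I) < spec$prop_polytomous,
                          "GPCM", "2PL")
    items$a <- stats::rlnorm(I, spec$a_meanlog, spec$a_sdlog)
    items$b <- stats::rnorm(I, spec$b_mean, spec$b_sd)
    items$steps <- lapply(seq_len(I), function(i) {
      if (items$model[i] == "GPCM")
        stats::rnorm(spec$n_categories - 1L, 0, spec$step_sd)
      else numeric(0)
    })
    items$subpool <- NA_character_
    for (att in names(spec$attribute_frequencies)) {
      p <- spec$attribute_frequencies[[att]]
      items[[att]] <- sample(names(p), I, replace = TRUE, prob = p)
    }
    pool <- hat_pool(items,
                     units = data.frame(unit_id = unit_ids,
                                        stringsAsFactors = FALSE),
                     domain = domain)
    if (!is.null(blueprint)) {
      blueprint <- as_blueprint(blueprint)
      check_blueprint_attributes(pool, blueprint)
      cat_rows <- blueprint[blueprint$level == "item_count" &
                              nzchar(blueprint$attribute), , drop = FALSE]
      for (k in seq_len(nrow(cat_rows))) {
        cs <- cat_rows[k, ]
        cnt <- sum(constraint_matches(cs, pool$items))
        need <- ceiling(spec$margin * cs$lb)
        if (cnt < need)
          stop_hat(sprintf(
            "generated pool too small for constraint %s (%s=%s): %d qualifying item(s), need %d (margin %.2f over lb %d); increase n_units or the category frequency",
            cs$constraint_id, cs$attribute, cs$value, cnt, need,
            spec$margin, cs$lb), "hatcat_generation_error")
      }
      fz <- validate_feasibility(pool, blueprint)
      if (!attr(fz, "feasible"))
        stop_hat(paste0("generated pool fails necessary feasibility for: ",
                        paste(fz$constraint_id[!fz$satisfied],
                              collapse = ", ")),
                 "hatcat_generation_error")
    }
    pool
  })
}
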