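# small deterministic pools and independent oracles used across the suite

# hand-authored 2-unit / 6-item pool with one polytomous item
tiny_pool <- function() {
  items <- data.frame(
    item_id = sprintf("T%02d", 1:6),
    unit_id = rep(c("U1", "U2"), each = 3),
    model = c("2PL", "2PL", "GPCM", "2PL", "2PL", "2PL"),
    a = c(1.0, 1.4, 0.8, 1.2, 0.9, 1.1),
    b = c(0.0, -0.5, 0.3, 0.8, -1.0, 0.2),
    stringsAsFactors = FALSE)
  items$steps <- list(numeric(0), numeric(0), c(0.4, -0.4),
                      numeric(0), numeric(0), numeric(0))
  items$proc <- c("Scan", "Rep", "Scan", "Rep", "Scan", "Rep")
  hat_pool(items, domain = "TOY")
}

# random unit-nested pool for property tests
random_pool <- function(n_units, items_per_unit = 2, prop_poly = 0,
                        domain = "RND") {
  I <- n_units * items_per_unit
  items <- data.frame(
    item_id = sprintf("R%03d", seq_len(I)),
    unit_id = rep(sprintf("U%02d", seq_len(n_units)),
                  each = items_per_unit),
    model = ifelse(runif(I) < prop_poly, "GPCM", "2PL"),
    a = rlnorm(I, 0, 0.3),
    b = rnorm(I),
    stringsAsFactors = FALSE)
  items$steps <- lapply(seq_len(I), function(i)
    if (items$model[i] == "GPCM") rnorm(2, 0, 0.5) else numeric(0))
  items$proc <- sample(c("Scan", "Rep"), I, replace = TRUE)
  hat_pool(items, domain = domain)
}

# a small blueprint over the random pool's "proc" attribute
toy_blueprint <- function(t, n_units, per_unit, proc_lb = 0, proc_ub = t) {
  hat_blueprint(data.frame(
    constraint_id = c("C1", "C2", "C3", "C4"),
    description = "",
    level = c("item_count", "unit_count", "per_unit_count", "item_count"),
    attribute = c("", "", "", "proc"),
    value = c("", "", "", "Scan"),
    lb = c(t, n_units[1], per_unit[1], proc_lb),
    ub = c(t, n_units[2], per_unit[2], proc_ub),
    stringsAsFactors = FALSE))
}

# --- independent compliance checker (plain counting, no package logic) ---
oracle_compliant <- function(ids, pool, bp) {
  it <- pool$items[pool$items$item_id %in% ids, ]
  for (k in seq_len(nrow(bp))) {
    r <- bp[k, ]
    if (r$level == "item_count") {
      cnt <- if (nzchar(r$attribute))
        sum(it[[r$attribute]] %in% strsplit(r$value, "|", fixed = TRUE)[[1]])
      else nrow(it)
      if (cnt < r$lb || cnt > r$ub) return(FALSE)
    } else if (r$level == "unit_count") {
      cnt <- length(unique(it$unit_id))
      if (cnt < r$lb || cnt > r$ub) return(FALSE)
    } else {
      tab <- table(it$unit_id)
      if (any(tab < r$lb) || any(tab > r$ub)) return(FALSE)
    }
  }
  TRUE
}

# exhaustive-enumeration assembly oracle: best feasible subset of size t
oracle_best_subset <- function(pool, bp, theta, rp = 0.5) {
  t <- bp$lb[bp$level == "item_count" & !nzchar(bp$attribute)][1]
  ids <- pool$items$item_id
  infos <- sapply(seq_len(nrow(pool$items)), function(i) {
    it <- pool$items[i, ]
    d <- if (rp == 0.5) 0 else log(rp / (1 - rp)) / it$a
    hatcat::fisher_information(it, theta - d)
  })
  names(infos) <- ids
  best <- -Inf
  for (comb in utils::combn(length(ids), t, simplify = FALSE)) {
    sel <- ids[comb]
    if (oracle_compliant(sel, pool, bp)) {
      v <- sum(infos[sel])
      if (v > best) best <- v
    }
  }
  best
}

# step-by-step reference maximum-information CAT (no shadow, no exposure
# control), used to validate the degenerate administration loop
oracle_max_info_cat <- function(pool, t, responses_by_id, prior_mean = 0) {
  administered <- character(0)
  scores <- integer(0)
  theta <- prior_mean
  g <- seq(-4, 4, length.out = 81)
  for (p in seq_len(t)) {
    cand <- setdiff(pool$items$item_id, administered)
    it <- pool$items[match(cand, pool$items$item_id), ]
    info <- it$a^2 * plogis(it$a * theta - it$b) *
      (1 - plogis(it$a * theta - it$b))
    pick <- sort(cand[info >= max(info) - 1e-12])[1]
    administered <- c(administered, pick)
    scores <- c(scores, responses_by_id[[pick]])
    adm <- pool$items[match(administered, pool$items$item_id), ]
    ll <- rep(0, length(g))
    for (i in seq_len(nrow(adm))) {
      pr <- plogis(adm$a[i] * g - adm$b[i])
      ll <- ll + if (scores[i] > 0) log(pr) else log(1 - pr)
    }
    w <- exp(ll + dnorm(g, prior_mean, 1, log = TRUE))
    w <- w / sum(w)
    theta <- sum(g * w)
  }
  list(sequence = administered, theta = theta)
}
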