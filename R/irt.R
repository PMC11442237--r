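#' Response probability under the two-parameter logistic model
#'
#' Probability of a correct response for a dichotomous item in
#' slope-intercept form: \eqn{P(\theta) = \mathrm{logit}^{-1}(a\theta - b)}.
#' The difficulty \code{b} lives on the logit scale (the information of the
#' item peaks at \eqn{\theta = b/a}).
#'
#' @param theta Ability value(s) on the logit scale.
#' @param a Discrimination, strictly positive.
#' @param b Difficulty (intercept) on the logit scale.
#' @return Probability in (0, 1), vectorized over `theta`.
#' @examples
#' prob_dichotomous(0, a = 1, b = 0)      # 0.5
#' prob_dichotomous(log(.62/.38), 1, 0)   # 0.62
#' @export
prob_dichotomous <- function(theta, a, b) {
  if (any(a <= 0)) stop_hat("discrimination 'a' must be positive",
                            "hatcat_domain_error")
  stats::plogis(a * theta - b)
}

#' Category probabilities under the generalized partial credit model
#'
#' Muraki-form GPCM with a common discrimination: for category score
#' \eqn{c \in \{0, \dots, m\}} the numerator is
#' \eqn{\exp\{\sum_{v=1}^{c} a(\theta - b + d_v)\}} with step parameters
#' \eqn{d_v} (the empty sum for \eqn{c = 0} is zero). With a single step at
#' zero the model reduces to the 2PL.
#'
#' @param theta Scalar ability.
#' @param a Discrimination, positive.
#' @param b Overall item difficulty.
#' @param steps Numeric vector of step parameters, length = categories - 1.
#' @return Vector of category probabilities summing to one.
#' @export
prob_polytomous <- function(theta, a, b, steps) {
  if (a <= 0) stop_hat("discrimination 'a' must be positive",
                       "hatcat_domain_error")
  if (length(steps) < 1) stop_hat("polytomous items need at least one step",
                                  "hatcat_domain_error")
  num <- c(0, cumsum(a * (theta - b + steps)))
  num <- num - max(num)                       # log-sum-exp stabilization
  e <- exp(num)
  e / sum(e)
}

# grid-vectorized GPCM: matrix length(thetas) x (m + 1)
gpcm_prob_grid <- function(thetas, a, b, steps) {
  cum <- c(0, cumsum(a * (-b + steps)))
  sc <- a * (0:length(steps))
  num <- outer(thetas, sc) + rep(cum, each = length(thetas))
  num <- num - apply(num, 1, max)
  e <- exp(num)
  e / rowSums(e)
}

#' Fisher information of an item at a given ability
#'
#' Dichotomous (2PL) items: \eqn{I(\theta) = a^2 P(\theta) Q(\theta)}.
#' Polytomous (GPCM) items with common discrimination:
#' \eqn{I(\theta) = a^2 \mathrm{Var}(X \mid \theta)} where \eqn{X} is the
#' category score.
#'
#' @param item A single-row item as produced by [hat_pool()] pools (a list or
#'   one-row data frame with `model`, `a`, `b`, `steps`).
#' @param theta Ability value(s).
#' @return Non-negative information, vectorized over `theta`.
#' @export
fisher_information <- function(item, theta) {
  it <- as_item(item)
  if (it$model == "2PL") {
    p <- prob_dichotomous(theta, it$a, it$b)
    it$a^2 * p * (1 - p)
  } else {
    pr <- gpcm_prob_grid(theta, it$a, it$b, it$steps)
    sc <- 0:length(it$steps)
    ex <- drop(pr %*% sc)
    ex2 <- drop(pr %*% sc^2)
    it$a^2 * (ex2 - ex^2)
  }
}

as_item <- function(item) {
  if (is.data.frame(item)) {
    stopifnot(nrow(item) == 1)
    st <- item$steps
    if (is.list(st)) st <- st[[1]]
    list(model = item$model, a = item$a, b = item$b, steps = st)
  } else {
    item$steps <- item$steps %||% numeric(0)
    item
  }
}

#' Selection configuration: target response probability
#'
#' @param rp Desired response probability in (0, 1). The default .62 matches
#'   the probability used to define proficiency levels in PISA reporting;
#'   .5 reduces shifted selection to plain maximum information.
#' @return An object of class `hat_rp`.
#' @export
rp_config <- function(rp = 0.62) {
  if (!is.numeric(rp) || length(rp) != 1 || rp <= 0 || rp >= 1)
    stop_hat("rp must be a single probability strictly inside (0, 1)",
             "hatcat_domain_error")
  structure(list(rp = rp), class = "hat_rp")
}

#' Ability shift targeting a desired response probability
#'
#' For a 2PL item the information-maximizing point sits where the success
#' probability is .5; evaluating information at \eqn{\hat\theta - \delta}
#' with \eqn{\delta = a^{-1} \log\{p/(1-p)\}} instead selects items whose
#' success probability at \eqn{\hat\theta} is the target \eqn{p}.
#'
#' @param a Discrimination, positive.
#' @param rp Target response probability in (0, 1).
#' @return The shift \eqn{\delta} (positive for rp > .5).
#' @examples
#' rp_shift(1, .62)   # log(.62/.38)
#' rp_shift(2, .62)   # half of that
#' @export
rp_shift <- function(a, rp) {
  if (any(a <= 0)) stop_hat("discrimination 'a' must be positive",
                            "hatcat_domain_error")
  if (any(rp <= 0) || any(rp >= 1))
    stop_hat("rp must lie strictly inside (0, 1)", "hatcat_domain_error")
  (1 / a) * log(rp / (1 - rp))
}

#' Fisher information at the RP-shifted ability
#'
#' Evaluates [fisher_information()] at \eqn{\hat\theta - \delta} where
#' \eqn{\delta} is the item's [rp_shift()]. With rp = .5 this equals the
#' unshifted information. The same \eqn{a}-based shift is applied to GPCM
#' items (the shift is defined from the discrimination alone).
#'
#' @param item Item (as in [fisher_information()]).
#' @param theta_hat Current provisional ability estimate.
#' @param rpconfig An [rp_config()] object.
#' @return Non-negative information value.
#' @export
shifted_information <- function(item, theta_hat, rpconfig = rp_config()) {
  it <- as_item(item)
  fisher_information(it, theta_hat - rp_shift(it$a, rpconfig$rp))
}

# vectorized over a pool's item table; returns named vector of (optionally
# RP-shifted) informations -- the selection currency used everywhere
pool_information <- function(items, theta_hat, rp = 0.5) {
  delta <- if (rp == 0.5) rep(0, nrow(items)) else log(rp / (1 - rp)) / items$a
  th <- theta_hat - delta
  info <- numeric(nrow(items))
  dich <- items$model == "2PL"
  if (any(dich)) {
    p <- stats::plogis(items$a[dich] * th[dich] - items$b[dich])
    info[dich] <- items$a[dich]^2 * p * (1 - p)
  }
  for (i in which(!dich)) {
    pr <- prob_polytomous(th[i], items$a[i], items$b[i], items$steps[[i]])
    sc <- 0:(length(pr) - 1)
    info[i] <- items$a[i]^2 * (sum(pr * sc^2) - sum(pr * sc)^2)
  }
  stats::setNames(info, items$item_id)
}

#' Prior specification for the latent abilities
#'
#' A D-dimensional normal prior. During administration only the
#' unidimensional marginal of the current domain is used; the full
#' covariance describes how simulees are generated and how ability carries
#' across domains.
#'
#' @param mean Mean vector (length D).
#' @param cov Covariance matrix (D x D), symmetric positive definite.
#' @return An object of class `hat_prior`.
#' @export
prior_spec <- function(mean = 0, cov = diag(length(mean))) {
  mean <- as.numeric(mean)
  cov <- as.matrix(cov)
  d <- length(mean)
  if (!all(dim(cov) == d))
    stop_hat("cov must be D x D for a D-vector mean", "hatcat_domain_error")
  if (max(abs(cov - t(cov))) > 1e-8)
    stop_hat("cov must be symmetric", "hatcat_domain_error")
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop_hat("cov must be positive definite", "hatcat_domain_error")
  structure(list(mean = mean, cov = cov, dim = d), class = "hat_prior")
}

#' Ability estimation from scored responses
#'
#' EAP integrates the posterior over an equally spaced quadrature grid with
#' a normal prior (the unidimensional marginal of `prior`); it is finite for
#' all response patterns and is the estimator used during administration.
#' MLE maximizes the log-likelihood inside the grid range and signals an
#' error of class `hatcat_mle_nonfinite` for all-correct / all-incorrect
#' patterns (callers fall back to EAP).
#'
#' @param items Item table (zero or more rows with `model`, `a`, `b`,
#'   `steps`), aligned with `scores`.
#' @param scores Integer observed scores (0/1 for 2PL, 0..m for GPCM).
#' @param method "EAP" or "MLE".
#' @param prior A [prior_spec()]; its first marginal is used.
#' @param grid Quadrature range (logits).
#' @param n_grid Number of grid points.
#' @return An object of class `hat_theta`: list(value, se, method,
#'   n_responses).
#' @export
estimate_theta <- function(items, scores, method = c("EAP", "MLE"),
                           prior = prior_spec(), grid = c(-4, 4),
                           n_grid = 81) {
  method <- match.arg(method)
  n <- if (is.null(items) || nrow(items) == 0) 0L else nrow(items)
  if (n != length(scores))
    stop_hat("items and scores must align", "hatcat_domain_error")
  g <- seq(grid[1], grid[2], length.out = n_grid)
  ll <- loglik_grid(items, scores, g)
  mu <- prior$mean[1]
  sd <- sqrt(prior$cov[1, 1])
  if (method == "EAP") {
    lpost <- ll + stats::dnorm(g, mu, sd, log = TRUE)
    w <- exp(lpost - max(lpost))
    w <- w / sum(w)
    val <- sum(g * w)
    se <- sqrt(sum((g - val)^2 * w))
    structure(list(value = val, se = se, method = "EAP", n_responses = n),
              class = "hat_theta")
  } else {
    if (n == 0)
      stop_hat("MLE undefined without responses", "hatcat_domain_error")
    i0 <- which.max(ll)
    if (i0 == 1L || i0 == n_grid)
      stop_hat("MLE non-finite for this response pattern (maximizer on the grid boundary)",
               "hatcat_mle_nonfinite")
    lo <- g[i0 - 1]; hi <- g[i0 + 1]
    op <- stats::optimize(function(th) loglik_grid(items, scores, th),
                          lower = lo, upper = hi, maximum = TRUE,
                          tol = 1e-8)
    se <- 1 / sqrt(max(sum(pool_information(items, op$maximum)), 1e-12))
    structure(list(value = op$maximum, se = se, method = "MLE",
                   n_responses = n), class = "hat_theta")
  }
}

# summed log-likelihood of the response pattern on a theta grid
loglik_grid <- function(items, scores, g) {
  ll <- numeric(length(g))
  if (is.null(items) || nrow(items) == 0) return(ll)
  for (i in seq_len(nrow(items))) {
    if (items$model[i] == "2PL") {
      p <- stats::plogis(items$a[i] * g - items$b[i])
      ll <- ll + if (scores[i] > 0) log(p) else log1p(-p)
    } else {
      pr <- gpcm_prob_grid(g, items$a[i], items$b[i], items$steps[[i]])
      ll <- ll + log(pr[, scores[i] + 1L])
    }
  }
  ll
}

#' @export
print.hat_theta <- function(x, ...) {
  cat(sprintf("theta estimate (%s): %.4f (se %.4f) from %d response(s)\n",
              x$method, x$value, x$se, x$n_responses))
  invisible(x)
}
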