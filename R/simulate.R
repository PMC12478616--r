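#' Simulate correlated binary attribute mastery patterns
#'
#' Draws each person's latent vector from a K-variate normal with zero
#' means, unit variances and compound-symmetry correlation `rho`, then
#' thresholds attribute `k` at \eqn{\Phi^{-1}(k/(K+1))}.  Marginal mastery
#' rates are therefore \eqn{1 - k/(K+1)}: later attributes are harder to
#' master, and `rho` controls only the dependence between attributes.
#'
#' @param N number of examinees.
#' @param K number of attributes.
#' @param rho common attribute correlation in \[0, 1).
#' @param seed optional integer seed.
#' @return An N x K binary matrix of attribute mastery patterns.
#' @examples
#' colMeans(simulate_attributes(5000, 4, 0, seed = 1))  # ~ (0.8, 0.6, 0.4, 0.2)
#' @export
simulate_attributes <- function(N, K, rho = 0, seed = NULL) {
  if (N < 1 || K < 1) stop("'N' and 'K' must be positive", call. = FALSE)
  if (rho < 0 || rho >= 1) stop("'rho' must lie in [0, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Sigma <- matrix(rho, K, K); diag(Sigma) <- 1
  Z <- matrix(stats::rnorm(N * K), N, K) %*% chol(Sigma)
  thr <- stats::qnorm(seq_len(K) / (K + 1))
  alpha <- (Z > matrix(thr, N, K, byrow = TRUE)) * 1L
  colnames(alpha) <- paste0("A", seq_len(K))
  alpha
}

#' Build a Q-matrix from an item-load composition
#'
#' Constructs a deterministic Q-matrix with `counts[m]` items requiring `m`
#' attributes each.  Single-attribute items first cover every attribute once
#' (an identity block, required for completeness) and then cycle over the
#' attributes; items with `m >= 2` cycle over the attribute combinations of
#' size `m` in lexicographic order.
#'
#' @param counts integer vector; `counts[m]` is the number of items loading
#'   on exactly `m` attributes.  `counts[1] >= K` is required so that every
#'   attribute is measured by at least one simple item.
#' @param K number of attributes.
#' @return A J x K binary Q-matrix with `J = sum(counts)`.
#' @examples
#' sim_q_matrix(c(8, 6, 5, 1), K = 4)  # the four-attribute factorial design
#' @export
sim_q_matrix <- function(counts, K) {
  counts <- as.integer(counts)
  if (any(counts < 0) || sum(counts) < 1)
    stop("'counts' must be non-negative with at least one item", call. = FALSE)
  if (length(counts) > K)
    stop("items cannot require more than K attributes", call. = FALSE)
  if (counts[1] < K)
    stop("composition must include at least one single-attribute item per ",
         "attribute (counts[1] >= K)", call. = FALSE)
  rows <- list()
  for (m in seq_along(counts)) {
    if (counts[m] == 0L) next
    combos <- utils::combn(K, m)
    idx <- rep(seq_len(ncol(combos)), length.out = counts[m])
    for (i in idx) {
      r <- integer(K); r[combos[, i]] <- 1L
      rows[[length(rows) + 1L]] <- r
    }
  }
  Q <- do.call(rbind, rows)
  dimnames(Q) <- list(paste0("item", seq_len(nrow(Q))), paste0("A", seq_len(K)))
  validate_q(Q)
}

#' Item response probability table for data generation
#'
#' Builds the \eqn{2^K} x J table of correct-response probabilities used to
#' generate data.  Under the DINA model the table is two-valued per item:
#' the low endpoint for every class missing a required attribute, the high
#' endpoint for full mastery.  Under the general monotone model an item
#' requiring `m` attributes gives each class a probability determined by how
#' many required attributes it masters: equally spaced between the endpoints
#' by default, or (with `jitter = TRUE`) drawn uniformly between them and
#' sorted so that the monotonicity partial order still holds.  Item quality
#' fixes the endpoints: `"high"` is (0.1, 0.9), `"low"` is (0.3, 0.7).
#'
#' @param Q J x K Q-matrix.
#' @param model `"dina"` or `"general"`.
#' @param quality `"high"` (endpoints 0.1/0.9) or `"low"` (0.3/0.7).
#' @param jitter randomize the intermediate levels of the general model.
#' @param seed optional integer seed (used only when `jitter = TRUE`).
#' @return A \eqn{2^K} x J matrix of probabilities in (0, 1) satisfying the
#'   monotonicity constraints (see [check_monotonicity()]).
#' @export
sim_item_probs <- function(Q, model = c("dina", "general"),
                           quality = c("high", "low"), jitter = FALSE,
                           seed = NULL) {
  model <- match.arg(model)
  quality <- match.arg(quality)
  Q <- validate_q(Q)
  if (!is.null(seed)) set.seed(seed)
  lo <- if (quality == "high") 0.1 else 0.3
  hi <- if (quality == "high") 0.9 else 0.7
  patterns <- attribute_patterns(ncol(Q))
  if (model == "dina") {
    theta <- lo + (hi - lo) * ideal_response(Q, "dina", patterns)
  } else {
    hits <- patterns %*% t(Q)
    need <- matrix(rowSums(Q), nrow(patterns), nrow(Q), byrow = TRUE)
    if (!jitter) {
      theta <- lo + (hi - lo) * hits / need
    } else {
      theta <- matrix(NA_real_, nrow(patterns), nrow(Q))
      for (j in seq_len(nrow(Q))) {
        m <- sum(Q[j, ])
        lev <- c(lo, if (m > 1) sort(stats::runif(m - 1, lo, hi)), hi)
        theta[, j] <- lev[hits[, j] + 1L]
      }
    }
  }
  dimnames(theta) <- list(rownames(patterns), rownames(Q))
  theta
}

#' Simulate item responses given patterns and an item probability table
#'
#' Each response is an independent Bernoulli draw with the probability the
#' person's latent class has for that item.
#'
#' @param alpha N x K binary attribute pattern matrix.
#' @param theta \eqn{2^K} x J item probability table in canonical class
#'   order.
#' @param seed optional integer seed.
#' @return An N x J binary response matrix.
#' @export
sim_responses <- function(alpha, theta, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- pattern_index(alpha)
  if (max(cls) > nrow(theta))
    stop("'theta' has too few rows for the pattern space of 'alpha'", call. = FALSE)
  P <- theta[cls, , drop = FALSE]
  X <- (matrix(stats::runif(length(P)), nrow(P), ncol(P)) < P) * 1L
  dimnames(X) <- list(NULL, colnames(theta))
  X
}

#' Simulate one dataset of a factorial recovery-study cell
#'
#' Convenience wrapper tying together [simulate_attributes()],
#' [sim_item_probs()] and [sim_responses()] for one cell of the factorial
#' design (generating model x Q composition x sample size x attribute
#' correlation x item quality).
#'
#' @param N sample size.
#' @param Q a Q-matrix, or an integer composition vector passed to
#'   [sim_q_matrix()] together with `K`.
#' @param K number of attributes (needed when `Q` is a composition).
#' @inheritParams sim_item_probs
#' @inheritParams simulate_attributes
#' @param seed integer seed governing all draws of the dataset.
#' @return A list of class `"dcm_sim"`: `alpha` (true patterns), `class`
#'   (true class indices), `theta`, `X`, `Q` and the design settings.
#' @export
sim_dcm <- function(N, Q, K = NULL, model = c("dina", "general"),
                    quality = c("high", "low"), rho = 0, jitter = FALSE,
                    seed = NULL) {
  model <- match.arg(model)
  quality <- match.arg(quality)
  if (!is.matrix(Q)) {
    if (is.null(K)) stop("'K' is required when 'Q' is a composition vector", call. = FALSE)
    Q <- sim_q_matrix(Q, K)
  }
  Q <- validate_q(Q)
  if (!is.null(seed)) set.seed(seed)
  alpha <- simulate_attributes(N, ncol(Q), rho)
  theta <- sim_item_probs(Q, model, quality, jitter)
  X <- sim_responses(alpha, theta)
  out <- list(alpha = alpha, class = pattern_index(alpha), theta = theta,
              X = X, Q = Q,
              design = list(N = N, model = model, quality = quality,
                            rho = rho, jitter = jitter, seed = seed))
  class(out) <- "dcm_sim"
  out
}

#' @export
print.dcm_sim <- function(x, ...) {
  cat(sprintf("Simulated DCM dataset: %d examinees, %d items, %d attributes\n",
              nrow(x$X), ncol(x$X), ncol(x$alpha)))
  cat(sprintf("  model %s, quality %s, rho %g, seed %s\n",
              x$design$model, x$design$quality, x$design$rho,
              if (is.null(x$design$seed)) "none" else x$design$seed))
  invisible(x)
}

#' Run one cell of the recovery simulation design over replications
#'
#' For each replication `r`, a dataset is generated with the derived seed
#' `seed + 7919 * r`, the requested estimators are fitted, and attribute-
#' and pattern-level agreement with the generating truth is scored.  GB
#' methods use their standard settings (1000 iterations, 500 burn-in, MH
#' step 0.05, learning rate 1, uniform Dirichlet, Beta(2, 1)) unless
#' overridden through `gb_args`.
#'
#' @inheritParams sim_dcm
#' @param methods subset of `"npc"`, `"gnpc"`, `"gbnpc"`, `"gbgnpc"`.
#' @param replications number of replications.
#' @param seed base seed; replication `r` uses `seed + 7919 * r`.
#' @param gb_args named list of overrides passed to [gbdcm()].
#' @return A list of class `"dcm_design"`: `results` (one row per
#'   replication x method: `aar`, `par`, and for GB methods the mean
#'   half-split correlation) and `aggregate` (means by method).
#' @export
run_design <- function(N, Q, K = NULL, model = c("dina", "general"),
                       quality = c("high", "low"), rho = 0,
                       methods = c("npc", "gnpc", "gbnpc", "gbgnpc"),
                       replications = 10L, seed = 1L, gb_args = list()) {
  model <- match.arg(model)
  quality <- match.arg(quality)
  methods <- match.arg(methods, several.ok = TRUE)
  rows <- list()
  for (r in seq_len(replications)) {
    rs <- seed + 7919L * r
    dat <- sim_dcm(N, Q, K, model, quality, rho, seed = rs)
    for (m in methods) {
      est <- switch(m,
        npc   = npc(dat$X, dat$Q)$pattern,
        gnpc  = gnpc(dat$X, dat$Q)$pattern,
        gbnpc = ,
        gbgnpc = {
          args <- c(list(X = dat$X, Q = dat$Q,
                         loss = if (m == "gbnpc") "hamming" else "sq_euclid",
                         seed = rs), gb_args)
          fit <- do.call(gbdcm, args)
          attr(fit$classification, "half_split") <- fit$half_split
          fit$classification
        })
      hs <- attr(est, "half_split")
      rows[[length(rows) + 1L]] <- data.frame(
        replication = r, method = m,
        aar = attribute_agreement(est, dat$alpha),
        par = pattern_agreement(est, dat$alpha),
        half_split = if (is.null(hs)) NA_real_ else mean(hs, na.rm = TRUE))
    }
  }
  results <- do.call(rbind, rows)
  aggregate <- do.call(rbind, lapply(split(results, results$method), function(d)
    data.frame(method = d$method[1L], aar = mean(d$aar), par = mean(d$par),
               half_split = mean(d$half_split))))
  rownames(aggregate) <- NULL
  out <- list(results = results, aggregate = aggregate,
              design = list(N = N, model = model, quality = quality, rho = rho,
                            replications = replications, seed = seed))
  class(out) <- "dcm_design"
  out
}

#' @export
print.dcm_design <- function(x, ...) {
  cat(sprintf("Recovery study cell: N=%d, model %s, quality %s, rho %g, %d replication(s)\n",
              x$design$N, x$design$model, x$design$quality, x$design$rho,
              x$design$replications))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}
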