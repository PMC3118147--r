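# GTR (4-state) and doublet (16-state) substitution models with
# discrete-gamma rate heterogeneity.
#
# Doublet state order: first base major, AA AC AG AU CA ... UU
# (state 4*x + y for bases coded A=0, C=1, G=2, U=3).

NUC <- c("A", "C", "G", "U")

#' Doublet state labels (AA, AC, ..., UU)
#' @return character vector of the 16 doublet states in package order.
#' @export
doublet_states <- function() {
  as.vector(t(outer(NUC, NUC, paste0)))
}

#' Empirical starting model from a partitioned alignment
#'
#' Stationary frequencies estimated from the data: base frequencies
#' from the unpaired columns and doublet frequencies from the paired
#' column pairs (pseudocount 0.5 per state), with equal
#' exchangeabilities. This is the default starting point for
#' [mcmc_run()]; the sampler's Dirichlet moves refine the frequencies
#' from there.
#'
#' @param aln a `structural_alignment`.
#' @param partition a [site_partition()].
#' @param alpha starting gamma shape (default 1).
#' @param ncat gamma categories (default 4).
#' @return a [subst_model()].
#' @export
empirical_subst_model <- function(aln, partition, alpha = 1, ncat = 4L) {
  m <- unclass(aln)
  up <- m[, partition$unpaired + 1L, drop = FALSE]
  bf <- table(factor(up[up != "-"], levels = NUC)) + 0.5
  df <- rep(0.5, 16)
  if (nrow(partition$pairs)) {
    a <- m[, partition$pairs[, 1] + 1L, drop = FALSE]
    b <- m[, partition$pairs[, 2] + 1L, drop = FALSE]
    ok <- a != "-" & b != "-"
    dl <- table(factor(paste0(a[ok], b[ok]), levels = doublet_states()))
    df <- df + as.numeric(dl)
  }
  subst_model(base_freqs = as.numeric(bf) / sum(bf),
              doublet_freqs = df / sum(df), alpha = alpha, ncat = ncat)
}

#' Doublet frequencies concentrated on canonical pairs
#'
#' Stationary doublet frequencies placing `canonical` total mass on the
#' four Watson-Crick pairs, `wobble` on GU/UG, and the remainder spread
#' over the ten mismatch doublets. This is what makes paired columns
#' covary: a stem column pair spends most of its time in canonical
#' states, and substitutions pass through wobble/mismatch intermediates.
#'
#' @param canonical total Watson-Crick mass (default 0.88).
#' @param wobble total GU+UG mass (default 0.08).
#' @return 16-simplex in [doublet_states()] order.
#' @export
doublet_freqs_canonical <- function(canonical = 0.88, wobble = 0.08) {
  stopifnot(canonical > 0, wobble >= 0, canonical + wobble < 1)
  st <- doublet_states()
  f <- rep((1 - canonical - wobble) / 10, 16)
  f[st %in% c("AU", "UA", "GC", "CG")] <- canonical / 4
  f[st %in% c("GU", "UG")] <- wobble / 2
  names(f) <- st
  f / sum(f)
}

#' Construct a partitioned substitution model
#'
#' A GTR model for unpaired columns and a 16-state doublet model for
#' paired columns, sharing the six exchangeabilities, plus a discrete
#' gamma distribution of site rates.
#'
#' @param exch six positive GTR exchangeabilities in the order AC, AG,
#'   AU, CG, CU, GU.
#' @param base_freqs stationary base frequencies (4-simplex).
#' @param doublet_freqs stationary doublet frequencies (16-simplex);
#'   default is the outer product of `base_freqs` (independence).
#' @param alpha gamma shape (> 0).
#' @param ncat number of discrete gamma categories (default 4).
#' @return list of class `subst_model`.
#' @export
subst_model <- function(exch = rep(1, 6), base_freqs = rep(0.25, 4),
                        doublet_freqs = NULL, alpha = 1, ncat = 4L) {
  stopifnot(length(exch) == 6, all(exch > 0),
            length(base_freqs) == 4, all(base_freqs > 0), alpha > 0)
  base_freqs <- base_freqs / sum(base_freqs)
  if (is.null(doublet_freqs)) {
    doublet_freqs <- as.vector(t(outer(base_freqs, base_freqs)))
  }
  stopifnot(length(doublet_freqs) == 16, all(doublet_freqs > 0))
  doublet_freqs <- doublet_freqs / sum(doublet_freqs)
  structure(list(exch = unname(exch), base_freqs = unname(base_freqs),
                 doublet_freqs = unname(doublet_freqs), alpha = alpha,
                 ncat = as.integer(ncat)),
            class = "subst_model")
}

# 4x4 symmetric exchangeability matrix from the 6-vector
exch_matrix <- function(exch) {
  R <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  ix <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  R[ix] <- exch
  R[ix[, 2:1]] <- exch
  R
}

#' GTR rate matrix
#'
#' `Q[x, y] = r(x, y) * pi(y)` for `x != y`, diagonal minus row sums,
#' rescaled so the mean rate at stationarity is 1
#' (`sum(pi * diag(Q)) == -1`).
#'
#' @param model a [subst_model()] (or explicit `exch`/`freqs`).
#' @param rescale rescale to unit mean rate (default TRUE).
#' @return 4x4 rate matrix.
#' @export
gtr_rate_matrix <- function(model, rescale = TRUE) {
  R <- exch_matrix(model$exch)
  Q <- R * rep(model$base_freqs, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (rescale) Q <- Q / sum(model$base_freqs * -diag(Q))
  Q
}

#' 16-state doublet rate matrix
#'
#' Single-position substitutions only: the rate from doublet `xy` to
#' `x'y` is `r(x, x') * pi16(x'y)` (likewise for the second position);
#' simultaneous changes of both positions have rate zero. The matrix is
#' time-reversible with respect to the doublet frequencies and rescaled
#' to unit mean rate at stationarity.
#'
#' @param model a [subst_model()].
#' @param rescale rescale to unit mean rate (default TRUE).
#' @return 16x16 rate matrix with dimnames [doublet_states()].
#' @export
doublet_rate_matrix <- function(model, rescale = TRUE) {
  R <- exch_matrix(model$exch)
  pi16 <- model$doublet_freqs
  Q <- matrix(0, 16, 16, dimnames = list(doublet_states(), doublet_states()))
  for (a in 0:15) {
    x <- a %/% 4L; y <- a %% 4L
    for (b in 0:15) {
      if (a == b) next
      u <- b %/% 4L; v <- b %% 4L
      if (y == v && x != u) Q[a + 1, b + 1] <- R[x + 1, u + 1] * pi16[b + 1]
      if (x == u && y != v) Q[a + 1, b + 1] <- R[y + 1, v + 1] * pi16[b + 1]
    }
  }
  diag(Q) <- -rowSums(Q)
  if (rescale) Q <- Q / sum(pi16 * -diag(Q))
  Q
}

#' Discrete-gamma category rates (mean-of-bin)
#'
#' K equal-probability quantile bins of a Gamma(shape = alpha,
#' rate = alpha) distribution; the category rate is the exact
#' conditional mean of its bin, so the K rates average exactly 1.
#'
#' @param alpha gamma shape (> 0).
#' @param K number of categories (default 4).
#' @param median_rates use bin medians instead of means.
#' @return numeric vector of K rates.
#' @export
discrete_gamma <- function(alpha, K = 4L) {
  if (alpha <= 0) stop("gamma shape must be positive")
  b <- stats::qgamma(seq_len(K - 1L) / K, shape = alpha, rate = alpha)
  bounds <- c(0, b, Inf)
  # E[X | bin] via the incomplete-gamma identity:
  # integral of x f(x) over bin = P(alpha + 1)-mass of the bin (rate kept)
  mass <- stats::pgamma(bounds, shape = alpha + 1, rate = alpha)
  K * diff(mass)
}

# spectral decomposition of a reversible rate matrix; P(t) follows by
# exponentiating the eigenvalues
decompose_rates <- function(Q, freqs) {
  d <- sqrt(freqs)
  S <- Q * (d %o% (1 / d))
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(U = (1 / d) * e$vectors, Uinv = t(e$vectors) * rep(d, each = length(d)),
       lambda = e$values)
}

#' Transition probability matrix of a reversible model
#'
#' @param Q rate matrix (from [gtr_rate_matrix()] or
#'   [doublet_rate_matrix()]).
#' @param freqs its stationary frequencies.
#' @param t branch length (expected substitutions per site).
#' @return stochastic matrix `exp(Q t)`.
#' @export
transition_prob <- function(Q, freqs, t) {
  dec <- decompose_rates(Q, freqs)
  P <- dec$U %*% (exp(dec$lambda * t) * dec$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Site partition into unpaired columns and doublet column pairs
#'
#' @param n_cols number of alignment columns.
#' @param pairs two-column matrix of 0-based paired column indices
#'   (non-crossing), e.g. from [detect_pairs()] or a consensus
#'   structure; may have zero rows.
#' @param unpaired 0-based indices of unpaired columns; default is every
#'   column not in `pairs`.
#' @return list of class `site_partition` with `unpaired` and `pairs`.
#' @export
site_partition <- function(n_cols, pairs = NULL, unpaired = NULL) {
  pairs <- if (is.null(pairs) || !length(pairs)) {
    matrix(integer(0), ncol = 2)
  } else matrix(as.integer(pairs), ncol = 2)
  used <- as.vector(pairs)
  if (anyDuplicated(used)) stop("column in more than one pair")
  if (length(used) && (any(used < 0) || any(used >= n_cols))) {
    stop("pair column out of range")
  }
  if (nrow(pairs)) {
    secondary_structure(pairs, n_cols, min_loop = 0L)  # non-crossing check
  }
  if (is.null(unpaired)) unpaired <- setdiff(seq_len(n_cols) - 1L, used)
  if (length(intersect(unpaired, used))) stop("partitions must be disjoint")
  structure(list(n_cols = as.integer(n_cols),
                 unpaired = as.integer(sort(unpaired)), pairs = pairs),
            class = "site_partition")
}

#' Site partition from a consensus dot-bracket structure
#'
#' @param ss_cons dot-bracket string over the alignment columns.
#' @return a [site_partition()].
#' @export
partition_from_structure <- function(ss_cons) {
  ss <- parse_dotbracket(ss_cons)
  site_partition(ss$length, pairs = ss$pairs)
}
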