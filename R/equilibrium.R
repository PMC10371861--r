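#' Build the 16x16 dinucleotide mutation rate matrix
#'
#' The rate from dinucleotide X to Y is the normalized rate of the unique
#' single-base mutation class converting X to Y (structural zero when X and
#' Y differ at both positions); the diagonal is set so rows sum to zero,
#' giving a continuous-time rate matrix.
#'
#' @param spectrum a \code{DiSpectrum96}.
#' @return a \code{\linkS4class{MutationMatrix16}}.
#' @export
buildRateMatrix <- function(spectrum) {
  cls <- spectrum@classes
  r <- spectrum@normalized_rate
  r[is.na(r)] <- 0
  if (all(r == 0)) stop("all normalized rates are zero")
  Q <- matrix(0, 16, 16, dimnames = list(DINUCS, DINUCS))
  for (i in seq_len(96)) Q[cls$dinuc[i], cls$resolved[i]] <- r[i]
  diag(Q) <- -rowSums(Q)
  new("MutationMatrix16", rates = Q, states = DINUCS)
}

## strongly-connected check of the positive-rate graph
.isIrreducible <- function(Q) {
  adj <- Q > 0
  diag(adj) <- FALSE
  reach <- function(a) {
    seen <- rep(FALSE, nrow(a)); seen[1] <- TRUE
    repeat {
      new <- (seen %*% a) > 0
      if (!any(new & !seen)) return(seen)
      seen <- seen | as.vector(new)
    }
  }
  fw <- reach(adj)
  bw <- reach(t(adj))
  list(ok = all(fw) && all(bw), component = which(fw & bw))
}

#' Stationary distribution of a dinucleotide rate matrix
#'
#' Solves pi . Q = 0 with sum(pi) = 1 for the unique stationary probability
#' vector of the embedded chain, after checking irreducibility of the
#' positive-rate graph. The linear solve is cross-checked internally by
#' power iteration on I + dt*Q.
#'
#' @param matrix a \code{MutationMatrix16} (or bare 16x16 rate matrix).
#' @return named numeric(16) of equilibrium dinucleotide frequencies.
#' @export
stationaryDistribution <- function(matrix) {
  Q <- if (is(matrix, "MutationMatrix16")) matrix@rates else matrix
  irr <- .isIrreducible(Q)
  if (!irr$ok)
    stop("rate matrix is reducible; reachable component: ",
         paste(colnames(Q)[irr$component], collapse = ","))
  M <- t(Q)
  M[nrow(M), ] <- 1
  b <- c(rep(0, nrow(M) - 1L), 1)
  pi_solve <- solve(M, b)
  pi_solve[pi_solve < 0 & pi_solve > -1e-12] <- 0
  pi_solve <- pi_solve / sum(pi_solve)
  ## cross-check by power iteration
  dt <- 0.5 / max(abs(diag(Q)))
  P <- diag(nrow(Q)) + dt * Q
  v <- rep(1 / nrow(Q), nrow(Q))
  for (i in seq_len(200000L)) {
    v2 <- as.vector(v %*% P)
    if (max(abs(v2 - v)) < 1e-14) { v <- v2; break }
    v <- v2
  }
  if (max(abs(v - pi_solve)) > 1e-6)
    stop("stationary solve and power iteration disagree")
  setNames(pi_solve, colnames(Q))
}

#' Equilibrium vs observed dinucleotide content
#'
#' Predicts the mutational-equilibrium dinucleotide frequencies from a rate
#' matrix, measures observed dinucleotide frequencies over intergenic space
#' (overlapping windows), fits predicted on observed by least squares over
#' the 16 states, and tests designated states (default AA and TT) as
#' outliers: each designated state's externally studentized prediction
#' residual from a fit excluding all designated states, two-sided p from
#' the t distribution, combined over the set by the maximum absolute
#' residual with a Sidak correction.
#'
#' @param matrix a \code{MutationMatrix16}.
#' @param genome \code{DNAStringSet}.
#' @param annotation annotation \code{GRanges} with intergenic rows.
#' @param outlier_states states to test (default \code{c("AA", "TT")}).
#' @return list with \code{predicted}, \code{observed}, \code{fit} (slope,
#'   intercept, r) and \code{outlier} (per-state t and p, joint p).
#' @export
equilibriumContent <- function(matrix, genome, annotation,
                               outlier_states = c("AA", "TT")) {
  predicted <- stationaryDistribution(matrix)
  ig <- resolveRegion(annotation, "intergenic")
  obs_counts <- countDinucs(intervalSeqs(genome, ig))
  if (any(obs_counts == 0))
    stop("degenerate observed frequencies: absent dinucleotide(s) ",
         paste(names(obs_counts)[obs_counts == 0], collapse = ","))
  observed <- obs_counts / sum(obs_counts)
  fit_all <- lm(predicted ~ observed)
  out <- outlierTest(predicted, observed, outlier_states)
  list(predicted = predicted, observed = observed,
       fit = list(slope = unname(coef(fit_all)[2]),
                  intercept = unname(coef(fit_all)[1]),
                  r = cor(predicted, observed)),
       outlier = out)
}

## externally studentized prediction residuals for designated states from a
## fit excluding them; joint p via max |t| with Sidak correction
outlierTest <- function(predicted, observed, states) {
  keep <- !(names(predicted) %in% states)
  if (sum(keep) < 4L) stop("too few states left after exclusion")
  x <- observed[keep]; y <- predicted[keep]
  fit <- lm(y ~ x)
  n <- sum(keep)
  s <- summary(fit)$sigma
  sxx <- sum((x - mean(x))^2)
  t_i <- vapply(states, function(st) {
    x0 <- observed[[st]]; y0 <- predicted[[st]]
    se <- s * sqrt(1 + 1 / n + (x0 - mean(x))^2 / sxx)
    (y0 - unname(coef(fit)[1] + coef(fit)[2] * x0)) / se
  }, 0)
  p_i <- 2 * pt(-abs(t_i), df = n - 2L)
  k <- length(states)
  list(t = t_i, p = p_i, p_joint = 1 - (1 - min(p_i))^k)
}
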