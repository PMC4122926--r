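# Amino-acid substitution model: WAG rate matrix, transition probabilities,
# stationary sampling.  Numerical core shared by the simulator, the distance
# estimators and the ancestral reconstruction engine.

# Parse a PAML-dialect amino-acid model file: 19 rows of lower-triangular
# exchangeabilities (residues in PAML order) followed by 20 equilibrium
# frequencies.  Returns values still in PAML residue order.
read_paml_dat <- function(path) {
  if (!file.exists(path))
    stop("substitution model file not found: ", path, call. = FALSE)
  tok <- scan(path, what = numeric(), quiet = TRUE)
  if (length(tok) != 190L + 20L)
    stop("corrupted substitution model file (expected 210 numbers, got ",
         length(tok), "): ", path, call. = FALSE)
  exch <- matrix(0, 20, 20)
  k <- 0L
  for (i in 2:20) for (j in 1:(i - 1L)) {
    k <- k + 1L
    exch[i, j] <- exch[j, i] <- tok[k]
  }
  list(exchangeabilities = exch, frequencies = tok[191:210])
}

#' Build the WAG amino-acid substitution model
#'
#' Constructs the Whelan-Goldman (WAG) general time-reversible amino-acid
#' model from the bundled exchangeability and equilibrium-frequency tables.
#' The generator matrix Q is assembled as \code{Q[i,j] = s[i,j] * pi[j]}
#' (i != j) with the diagonal set so rows sum to zero, and is rescaled so
#' that one unit of branch length corresponds to one expected substitution
#' per site at stationarity (\code{-sum(pi * diag(Q)) == 1}).  A symmetric
#' eigendecomposition of the similarity-transformed generator is precomputed
#' and stored, which makes transition matrices exact and cheap for any
#' branch length.
#'
#' @param dat_file Path to a PAML-dialect model file. Defaults to the
#'   bundled WAG table.
#' @return An object of class \code{subst_model}: a list with elements
#'   \code{name}, \code{alphabet}, \code{frequencies}, \code{exchangeabilities},
#'   \code{Q}, and the eigendecomposition used by
#'   \code{\link{transition_matrix}}.
#' @examples
#' m <- build_wag()
#' sum(m$frequencies)          # 1
#' range(rowSums(m$Q))         # ~0
#' @export
build_wag <- function(dat_file = system.file("extdata", "wag.dat",
                                             package = "ancprobe")) {
  raw <- read_paml_dat(dat_file)
  perm <- match(AA_ALPHABET20, PAML_AA_ORDER)
  s <- raw$exchangeabilities[perm, perm]
  f <- raw$frequencies[perm]
  if (any(f <= 0)) stop("equilibrium frequencies must all be positive",
                        call. = FALSE)
  f <- f / sum(f)
  q <- s * rep(f, each = 20)        # Q_ij = s_ij * pi_j
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  rate <- -sum(f * diag(q))
  q <- q / rate
  dimnames(q) <- list(AA_ALPHABET20, AA_ALPHABET20)
  # pi^{1/2} Q pi^{-1/2} is symmetric for reversible Q: real spectrum,
  # stable exponentials.
  sq <- sqrt(f)
  b <- q * (sq %o% (1 / sq))
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  structure(list(
    name = "WAG",
    alphabet = AA_ALPHABET20,
    frequencies = stats::setNames(f, AA_ALPHABET20),
    exchangeabilities = s,
    Q = q,
    eig_values = e$values,
    # P(t) = right %*% diag(exp(lambda t)) %*% left
    eig_right = e$vectors / sq,
    eig_left = t(e$vectors * sq)
  ), class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Amino-acid substitution model:", x$name, "\n")
  cat("  alphabet:", paste(x$alphabet, collapse = ""), "\n")
  cat("  rate normalization: ",
      format(-sum(x$frequencies * diag(x$Q)), digits = 10),
      " expected substitutions/site/unit time\n", sep = "")
  invisible(x)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A \code{subst_model}.
#' @param t Branch length in expected substitutions per site; finite, >= 0.
#' @return A 20 x 20 row-stochastic matrix in alphabet order.
#' @examples
#' m <- build_wag()
#' range(rowSums(transition_matrix(m, 0.3)))  # 1
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("branch length 't' must be a single finite number >= 0",
         call. = FALSE)
  p <- model$eig_right %*% (exp(model$eig_values * t) * model$eig_left)
  p[p < 0] <- 0
  p <- p / rowSums(p)
  dimnames(p) <- list(model$alphabet, model$alphabet)
  p
}

#' Sample a protein sequence from the stationary distribution
#'
#' Draws \code{length} residues i.i.d. from the model's equilibrium
#' frequencies; used for root sequences and non-homologous decoys.
#'
#' @param model A \code{subst_model}.
#' @param length Number of sites (>= 1).
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return A single character string of \code{length} residues.
#' @export
sample_stationary <- function(model, length, seed = NULL) {
  stopifnot(inherits(model, "subst_model"))
  if (!is.numeric(length) || length(length) != 1L || length < 1)
    stop("'length' must be >= 1", call. = FALSE)
  with_seed(seed, paste(sample(model$alphabet, as.integer(length),
                               replace = TRUE, prob = model$frequencies),
                        collapse = ""))
}
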