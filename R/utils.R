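#' @keywords internal
"_PACKAGE"

# Canonical clinical stage order used throughout the package.
STAGE_LEVELS <- c("Healthy", "AGA3", "AGA5", "AGA7")

# Short labels used in discordance flags ("H-A3", "A5-A7", ...).
STAGE_SHORT <- c(Healthy = "H", AGA3 = "A3", AGA5 = "A5", AGA7 = "A7")

KINGDOMS <- c("bacteria", "fungi")

TAXONOMIC_LEVELS <- c("kingdom", "phylum", "class", "order", "family",
                      "genus", "species")

#' Derive a reproducible child seed from a master seed and a stream name
#'
#' All stochastic operations in the package draw their seed from a master
#' seed through named streams, so that e.g. adding classifier repeats does
#' not reshuffle the synthetic cohort. The derivation is a fixed integer
#' hash; results stay within the 32-bit range R requires of `set.seed()`.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @param index optional integer sub-index (e.g. repeat number).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
seed_stream <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (abs(master) %% 2^20) * 1009 + h * 7919 + index * 104729
  as.integer(val %% (2^31 - 1))
}

stage_factor <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), STAGE_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown clinical stage(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = STAGE_LEVELS)
}

stage_rank <- function(stage) {
  match(as.character(stage), STAGE_LEVELS)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Draw one Dirichlet vector via independent gammas.
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) {
    # numerically degenerate draw (tiny alphas): fall back to the mean
    return(alpha / sum(alpha))
  }
  stats::setNames(g / sum(g), names(alpha))
}
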