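#' Derive a stage-specific seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from a master seed plus a stage label, so that a single integer
#' reproduces a whole run while stages remain independent.
#'
#' @param master Integer master seed.
#' @param stage Character stage label.
#' @param rep Optional replicate index folded into the seed.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master, stage, rep = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  val <- (abs(as.numeric(master)) * 69069 + h * 2654435761 + as.numeric(rep) * 97561) %%
    2147483629
  as.integer(val)
}

# Set the RNG locally if a seed is given; otherwise leave the global stream.
local_seed_if <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}

logit <- function(p) stats::qlogis(p)
inv_logit <- function(x) stats::plogis(x)

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
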