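#' @importFrom stats pnorm pchisq pt qnorm sd fisher.test setNames complete.cases
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

stop_config <- function(...) stop(errorCondition(paste0(...),
  class = c("mrtriad_config_error", "error")))

stop_input <- function(...) stop(errorCondition(paste0(...),
  class = c("mrtriad_input_error", "error")))

stop_param <- function(...) stop(errorCondition(paste0(...),
  class = c("mrtriad_param_error", "error")))

stop_instruments <- function(...) stop(errorCondition(paste0(...),
  class = c("mrtriad_insufficient_instruments", "error")))

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complement_allele <- function(a) unname(COMPLEMENT[a])

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

is_snv_allele <- function(a) !is.na(a) & a %in% names(COMPLEMENT)
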