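`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` in effect and restores the caller's
#' random-number stream afterwards, so seeded helpers do not perturb
#' surrounding simulations. A `NULL` seed evaluates `code` unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# structured progress/log line on stderr
wkde_log <- function(...) message("[wkdeclock] ", ...)

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

stop_wkde <- function(...) stop(..., call. = FALSE)
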