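#' @keywords internal
"_PACKAGE"

#' The four epileptic state labels
#'
#' Fixed label set, in the canonical order used throughout the package:
#' baseline between seizures, the 30-to-10-minute pre-onset window, the final
#' 10 minutes before onset, and the seizure itself.
#'
#' @return Character vector of length 4.
#' @export
state_labels <- function() {
  c("interictal", "preictal_I", "preictal_II", "seizure")
}

check_state <- function(state) {
  if (!(is.character(state) && length(state) == 1L && state %in% state_labels())) {
    stop("unknown state label '", paste(state, collapse = ","),
         "'; valid labels: ", paste(state_labels(), collapse = ", "),
         call. = FALSE)
  }
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# all generator randomness is scoped: callers never see a changed .Random.seed
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed %% .Machine$integer.max), code)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
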