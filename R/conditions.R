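# Classed error conditions so callers and tests can discriminate failure
# modes without matching on message text.

qlus_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "qlus_error"), call = call))
}

qlus_warn <- function(msg, class = "qlus_warning") {
  warning(warningCondition(msg, class = c(class, "qlus_warning")))
}

#' @noRd
assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    qlus_stop(sprintf("`%s` must be a single finite number", name),
              "qlus_value_error")
  }
}

# Deterministic child seeds: keeps every derived seed a positive 32-bit
# integer so the same master seed always reproduces the same stream.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + k) %% 2147483629 + 1)
}

# Evaluate `expr` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
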