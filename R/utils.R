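#' @keywords internal
"_PACKAGE"

# Run an expression under a local RNG state so generators are pure
# functions of their seed and never disturb the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Scatter-add: out[idx] += w with duplicate indices accumulated.
accumulate <- function(n, idx, w) {
  out <- numeric(n)
  s <- rowsum(w, group = idx)
  out[as.integer(rownames(s))] <- s[, 1L]
  out
}

stop_invalid <- function(...) {
  stop(structure(class = c("organoidmech_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
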