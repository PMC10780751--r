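# internal helpers

# run code under a fixed RNG seed, restoring the caller's RNG state
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# balance check used by analysis entry points (cheaper than full validation)
assert_balanced <- function(data) {
  need <- c("env", "gen", "yield")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- table(data$env, data$gen)
  if (length(unique(as.vector(n))) != 1 || any(n == 0)) {
    stop("balance error: not every (env, gen) cell has the same number of plots",
         call. = FALSE)
  }
  invisible(data)
}

# ranks with average ties
avg_rank <- function(x) rank(x, ties.method = "average")

# significance stars at the conventional thresholds
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p <= 0.001, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", ""))))
}
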