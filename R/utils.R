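# internal helpers: classed conditions and seed management

lw_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "latentWMW_error"),
                      call = call))
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Counter-based substream seeds: deterministic, collision-poor, < 2^31.
derive_seed <- function(base, counter) {
  v <- ((as.numeric(base) %% 2147483647) * 48271 +
          2654435 * as.numeric(counter) + as.numeric(counter)^2) %% 2147483629
  as.integer(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
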