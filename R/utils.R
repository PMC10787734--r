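# Internal helpers shared across modules.

# Canonical feature-column name for a bin mass (4 decimals, Da).
fmt_mass <- function(m) sprintf("%.4f", m)

# Fold a master seed and a few small integer coordinates into one
# reproducible 32-bit seed (kept strictly below 2^31).
derive_seed <- function(master, ...) {
  coords <- c(...)
  x <- as.double(master) %% 2147483647
  for (k in coords) {
    x <- (x * 69069 + as.double(k) * 9973 + 1) %% 2147483647
  }
  as.integer(x)
}

# Evaluate `expr` with the stage name attached to any error message.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Columns every specimen manifest / feature-matrix metadata block carries.
META_COLS <- c("specimen_id", "replicate_id", "species", "genus",
               "class", "phylum")
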