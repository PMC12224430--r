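# Internal helpers: input checks, seed streams, deterministic text output.

abort_input <- function(msg, class = "pecmap_invalid_input") {
  rlang::abort(msg, class = c(class, "pecmap_error"))
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || anyNA(x) || (finite && !all(is.finite(x)))) {
    abort_input(sprintf("`%s` must be finite numeric, got %s.", name,
                        paste(utils::head(x, 3), collapse = ", ")))
  }
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed; each component
#' (mesh jitter, montage placement, outcome noise, permutations, replicate k)
#' draws from its own stream derived here, so that e.g. adding permutations
#' does not perturb the generated outcome table.
#'
#' @param seed Master seed (integer).
#' @param stream Character stream label, e.g. `"noise"`, `"perm"`.
#' @param index Optional integer index (replicate number).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stream, index = 0L) {
  check_number(seed, "seed")
  # small multiplicative hash over the stream label; stable across platforms
  h <- sum(as.integer(charToRaw(stream)) * seq_along(charToRaw(stream)))
  (abs(as.integer(seed)) %% 1000003L) * 2017L + h * 131L + as.integer(index) * 7919L
}

with_stream_seed <- function(seed, stream, index = 0L, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, stream, index))
  force(code)
}

# Interpolated quantile (type 7): the package-wide convention, recorded in
# all run summaries.
pec_quantile <- function(x, p) {
  unname(stats::quantile(x, probs = p, type = 7, names = FALSE))
}

# Fixed-format numeric rendering so that repeated runs are byte-identical.
fmt_num <- function(x, digits = 12) {
  formatC(x, digits = digits, format = "g")
}

write_tsv_exact <- function(df, path, digits = 12) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]], digits)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
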