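#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed for a named component so that one global seed
# drives every random stage through independent, reproducible streams.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
component_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  codes <- utf8ToInt(component)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

# Total deterministic ordering used by every top-k selection:
# ascending p, then descending magnitude (fold change or overlap),
# then ascending id. Returns a permutation of seq_along(p).
rank_order <- function(p, magnitude, id) {
  order(p, -magnitude, id, method = "radix")
}

# Full-precision numeric formatting so that written tables and graphs
# round-trip doubles exactly.
num_fmt <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

write_tsv <- function(df, path) {
  is_num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[is_num] <- lapply(df[is_num], num_fmt)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}
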