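# Shared constants and small internal helpers.

# The 20 standard residues, the ambiguity codes tolerated on input, and the
# Kyte-Doolittle hydropathy scale used by the built-in detectability voter.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_AMBIGUOUS <- c("B", "J", "O", "U", "X", "Z")

KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

`%||%` <- function(a, b) if (is.null(a)) b else a

has_ambiguous_residue <- function(x) grepl("[BJOUXZ]", x)

# Locale-independent string ordering so every ranking and report is
# byte-identical across machines.
order_radix <- function(...) order(..., method = "radix")

collapse_set <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_character_)
  paste(sort(unique(x), method = "radix"), collapse = ";")
}

# Deterministic TSV writer used by every report file.
write_tsv_file <- function(df, path) {
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

wrap_fasta <- function(x, width = 60L) {
  if (nchar(x) <= width) return(x)
  starts <- seq(1L, nchar(x), by = width)
  vapply(starts, function(s) substr(x, s, min(s + width - 1L, nchar(x))),
         character(1))
}
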