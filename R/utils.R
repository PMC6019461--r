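# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

# sense codons (no stop) used when synthesizing open reading frames
SENSE_CODONS <- local({
  all3 <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_maf <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mafseq_error")))
}

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` after `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library functions do not perturb user simulations.
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

random_nt <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(width), function(j) m[, j, drop = TRUE]))
}

random_sense_codons <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Reverse complement
#' @param x character vector of nucleotide strings
#' @return character vector
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate in-frame nucleotide strings
#'
#' Standard-code translation; codons with ambiguous bases give `X`,
#' stops give `*`. Strings whose length is not a multiple of three
#' translate to `NA`.
#' @param x character vector of nucleotide strings
#' @return character vector of amino-acid strings
#' @export
translate_nt <- function(x) {
  gc <- Biostrings::GENETIC_CODE  # plain named vector
  out <- rep(NA_character_, length(x))
  ok <- which(!is.na(x) & nchar(x) > 0 & nchar(x) %% 3 == 0)
  for (i in ok) {
    n <- nchar(x[i])
    codons <- substring(x[i], seq(1L, n, 3L), seq(3L, n, 3L))
    aa <- unname(gc[codons])
    aa[is.na(aa)] <- "X"
    out[i] <- paste(aa, collapse = "")
  }
  out
}

phred_scores <- function(q) utf8ToInt(q) - 33L

mean_phred <- function(q) {
  vapply(q, function(s) mean(utf8ToInt(s)) - 33, numeric(1), USE.NAMES = FALSE)
}

qual_string <- function(scores) intToUtf8(scores + 33L)

# substitute random different bases at given 1-based positions of one string
substitute_bases <- function(seq, positions) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(0L)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
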