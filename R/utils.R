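# shared low-level helpers; DNA is handled as plain upper-case character
# strings internally, Biostrings only at I/O boundaries

.BASE_LOOKUP <- local({
  lk <- integer(256)
  lk[utf8ToInt("A")] <- 1L; lk[utf8ToInt("a")] <- 1L
  lk[utf8ToInt("C")] <- 2L; lk[utf8ToInt("c")] <- 2L
  lk[utf8ToInt("G")] <- 3L; lk[utf8ToInt("g")] <- 3L
  lk[utf8ToInt("T")] <- 4L; lk[utf8ToInt("t")] <- 4L
  lk
})

# A,C,G,T -> 1..4; any ambiguity code -> 0 (scores as background expectation)
encodeDNA <- function(seq) {
  if (!nzchar(seq)) return(integer(0))
  .BASE_LOOKUP[utf8ToInt(seq)]
}

decodeDNA <- function(enc) {
  paste(c("N", DNA_BASES)[enc + 1L], collapse = "")
}

#' Reverse complement of a DNA string
#'
#' Plain-character reverse complement; IUPAC ambiguity codes other than N
#' are mapped to N.
#'
#' @param x character(1) DNA sequence.
#' @return character(1).
#' @export
reverseComplement2 <- function(x) {
  enc <- encodeDNA(x)
  rc <- rev(ifelse(enc == 0L, 0L, 5L - enc))
  decodeDNA(rc)
}

# round half up on a fixed grid, deterministic for negative values too
.quantize <- function(x, binWidth) {
  q <- floor(x / binWidth + 0.5)
  storage.mode(q) <- "integer"
  q
}

.readSymbolList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}

.writeSymbolList <- function(x, path) writeLines(x, path)

# TSV with optional '#' provenance header lines
.writeTsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.readTsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

.matchCaseInsensitive <- function(query, reference) {
  match(toupper(query), toupper(reference))
}
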