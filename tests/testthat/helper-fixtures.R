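# Three 8-base records whose full signature landscape is known and small
# enough to verify by hand (and by the brute-force oracle).
toy_db <- function() {
  sig_db(c(seq1 = "CCCTAATG", seq2 = "TTAATAAT", seq3 = "ATAATGCG"))
}

# The 11-entry candidate-count example exercised by the PEL walkthrough.
pel_example_tasks <- function() {
  data.frame(id = LETTERS[1:11],
             count = c(33, 26, 49, 5, 143, 9, 72, 29, 11, 55, 22),
             stringsAsFactors = FALSE)
}

sig_strings <- function(s) s$members$string

# Signature-set members as an occurrence data.frame usable as candidates.
members_occ <- function(s) {
  data.frame(seq_index = s$members$seq_index, offset = s$members$offset,
             length = s$l)
}

# Naive substring scan used as the enumeration oracle for occurrences.
naive_substrings <- function(db, l) {
  unlist(lapply(db$seqs, function(s) {
    n <- nchar(s) - l + 1L
    if (n < 1L) character(0) else substring(s, 1:n, l:(l + n - 1L))
  }), use.names = FALSE)
}
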