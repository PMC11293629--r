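# Fixtures and independent oracles used across the suite. The oracles
# deliberately avoid the package's walk machinery: re-alphabeting goes
# through chartr(), k-mer counting through substring tables.

random_dna <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# chartr-based re-alphabeting, independent of transform_sequence()
oracle_transform <- function(seq, scheme_name) {
  from <- "ACGT"
  to <- switch(scheme_name,
               purine_pyrimidine = "RYRY",
               amino_keto = "MMKK",
               weak_strong = "WSSW")
  chartr(from, to, seq)
}

# naive dictionary k-mer counter over any alphabet: named counts of every
# overlapping window
oracle_kmer_table <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(table(character()))
  table(substring(seq, 1:(n - k + 1), k:n))
}

# naive elementwise Manhattan distance between two feature vectors
oracle_manhattan <- function(a, b) sum(abs(a - b))

write_tmp_fasta <- function(text) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(text, path)
  path
}
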