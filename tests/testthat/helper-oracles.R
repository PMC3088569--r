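# Independent oracles used across the suite. These deliberately avoid the
# implementation paths they check: alignment is verified against
# Biostrings::matchPattern over every chromosome and strand, and folding
# against exhaustive enumeration of all nested structures scored with the
# package's loop-decomposition evaluator.

# all exact-match loci of `query` in `g`, by full scan of both strands
oracle_hits <- function(g, query) {
  out <- list()
  for (chrom in names(g)) {
    subj <- Biostrings::DNAString(g[[chrom]])
    plus <- Biostrings::matchPattern(query, subj, fixed = TRUE)
    minus <- Biostrings::matchPattern(srnapipe::revcomp(query), subj, fixed = TRUE)
    if (length(plus)) {
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = chrom, start = BiocGenerics::start(plus), strand = "+")
    }
    if (length(minus)) {
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = chrom, start = BiocGenerics::start(minus), strand = "-")
    }
  }
  dplyr::arrange(dplyr::bind_rows(
    tibble::tibble(chrom = character(), start = integer(), strand = character()),
    out), chrom, start, strand)
}

# all nested pair sets over `seq` (pairable bases, min hairpin loop 3),
# returned as a list of 2-column matrices
enumerate_structures <- function(seq) {
  code <- local({
    s <- chartr("Tt", "Uu", toupper(seq))
    match(strsplit(s, "")[[1]], c("A", "C", "U", "G"))
  })
  can_pair <- function(a, b) {
    x <- paste0(c("A", "C", "U", "G")[a], c("A", "C", "U", "G")[b])
    x %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  n <- length(code)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1, j)  # i unpaired
    for (l in seq(i + 4, j)) {
      if (!can_pair(code[i], code[l])) next
      inner <- rec(i + 1, l - 1)
      rest <- if (l + 1 <= j) rec(l + 1, j) else list(matrix(integer(0), ncol = 2))
      for (a in inner) for (b in rest) {
        out[[length(out) + 1]] <- rbind(c(i, l), a, b)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1, n)
}

# minimum energy over all enumerated structures, scored independently of the
# DP by loop decomposition
oracle_mfe <- function(seq) {
  structs <- enumerate_structures(seq)
  energies <- vapply(structs, function(p) srnapipe::structure_energy(seq, p),
                     numeric(1))
  min(energies)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
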