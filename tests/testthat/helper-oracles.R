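# Independent oracles shared across test files: codon-site enumeration via
# seqinr translation, and the nearest-neighbor table typed afresh with its
# own summation code.

oracle_translate <- function(codon)
  seqinr::translate(strsplit(codon, "")[[1]])

oracle_sites <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    muts <- setdiff(c("A", "C", "G", "T"), ref)
    aas <- vapply(muts, function(b) {
      m <- codon; substr(m, pos, pos) <- b; oracle_translate(m)
    }, character(1))
    valid <- aas != "*"
    if (any(valid)) s <- s + sum(aas[valid] == aa) / sum(valid)
  }
  c(S = s, N = 3 - s)
}

all_sense_codons <- function() {
  cods <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                paste0), c("A", "C", "G", "T"), paste0))
  cods[vapply(cods, oracle_translate, character(1)) != "*"]
}

ORACLE_DG <- c(AA = -1.00, AT = -0.88, TA = -0.58, CA = -1.45, GT = -1.44,
               CT = -1.28, GA = -1.30, CG = -2.17, GC = -2.24, GG = -1.84,
               TT = -1.00, TG = -1.45, AC = -1.44, AG = -1.28, TC = -1.30,
               CC = -1.84)
ORACLE_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
               CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
               TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
               CC = -8.0)
ORACLE_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
               CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
               TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
               CC = -19.9)

oracle_sum <- function(seq, table, init_at, init_gc, sym) {
  v <- strsplit(seq, "")[[1]]
  stacks <- paste0(v[-length(v)], v[-1])
  init <- function(b) if (b %in% c("A", "T")) init_at else init_gc
  rc <- paste(rev(chartr("ACGT", "TGCA", v)), collapse = "")
  sum(table[stacks]) + init(v[1]) + init(v[length(v)]) +
    if (seq == rc) sym else 0
}
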