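## Genome containers, FASTA/annotation I/O, IUPAC motif scanning.
## Coordinates are 0-based, half-open, forward frame throughout; exported
## BED keeps that convention, exported GFF3 converts to 1-based inclusive.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' Construct a genome sequence object
#'
#' A genome is a single nucleotide sequence over `{A,C,G,T,N}` with an
#' identifier and a circularity flag.  Bacterial chromosomes are circular by
#' default, so motif windows and gene intervals may wrap across the origin.
#'
#' @param id Accession-style identifier.
#' @param seq Nucleotide sequence (character scalar); lowercase is accepted
#'   and normalised to uppercase.
#' @param circular Treat the sequence as a closed circle (default `TRUE`).
#' @return An object of class `genome_seq` with fields `id`, `seq`,
#'   `circular` and `length`.
#' @export
genome_sequence <- function(id, seq, circular = TRUE) {
  seq <- toupper(as.character(seq))
  if (length(seq) != 1L || nchar(seq) == 0L)
    stop("genome sequence must be a single non-empty string")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d (0-based %d)",
                 substr(seq, bad, bad), bad, bad - 1L))
  structure(
    list(id = as.character(id), seq = seq,
         circular = isTRUE(circular), length = nchar(seq)),
    class = "genome_seq"
  )
}

#' @export
print.genome_seq <- function(x, ...) {
  cat(sprintf("<genome_seq> %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Reads the first record of a FASTA file into a [genome_sequence()].  The
#' identifier is the first whitespace-delimited token of the header.
#'
#' @param path Path to a FASTA file.
#' @param circular Circularity flag passed to [genome_sequence()].
#' @return A `genome_seq` object.
#' @export
read_fasta <- function(path, circular = TRUE) {
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop(sprintf(
                   "cannot parse FASTA file '%s': %s", path, conditionMessage(e))))
  if (length(ss) == 0L)
    stop(sprintf("FASTA file '%s' contains no records", path))
  id <- strsplit(names(ss)[1L], "\\s+")[[1L]][1L]
  genome_sequence(id, as.character(ss[[1L]]), circular = circular)
}

#' Write a genome to a FASTA file
#'
#' @param genome A `genome_seq` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$seq)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Reverse complement of an IUPAC pattern
#'
#' Degenerate codes are complemented by their set complement (Y <-> R,
#' K <-> M, B <-> V, D <-> H; W, S and N are self-complementary), so the
#' result matches on the opposite strand exactly where the input matches on
#' the given strand.
#'
#' @param pattern Character scalar over IUPAC nucleotide codes.
#' @return The reverse-complemented pattern.
#' @export
reverse_complement_iupac <- function(pattern) {
  pattern <- toupper(as.character(pattern))
  chars <- strsplit(pattern, "")[[1L]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("invalid IUPAC code '%s' at position %d", chars[bad[1L]], bad[1L]))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
}

#' Construct an IUPAC motif with a methylated offset
#'
#' Describes a (possibly degenerate) recognition motif together with the
#' 0-based offset of the modified base within the pattern, e.g. the
#' bipartite type I R-M motif `CTAYNNNNNNNNTRTC` methylated at the adenine
#' at offset 2.
#'
#' @param pattern IUPAC pattern string.
#' @param methylated_offset 0-based index of the modified base.
#' @return An object of class `iupac_motif`.
#' @export
iupac_motif <- function(pattern, methylated_offset) {
  pattern <- toupper(as.character(pattern))
  chars <- strsplit(pattern, "")[[1L]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad))
    stop(sprintf("invalid IUPAC code '%s' at position %d", chars[bad[1L]], bad[1L]))
  methylated_offset <- as.integer(methylated_offset)
  if (methylated_offset < 0L || methylated_offset >= nchar(pattern))
    stop("methylated_offset must lie within the pattern")
  structure(
    list(pattern = pattern, methylated_offset = methylated_offset,
         length = nchar(pattern)),
    class = "iupac_motif"
  )
}

## matchPattern() starts for `pat` against the (possibly extended) subject,
## filtered so that genomic N never satisfies a non-N pattern code.
.scan_starts <- function(pat, subj_str, subj_dna, L) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj_dna,
                                   fixed = FALSE)
  st <- BiocGenerics::start(hits)
  st <- st[st <= L]                       # each circular window counted once
  if (!length(st)) return(integer(0))
  pv <- strsplit(pat, "")[[1L]]
  k <- nchar(pat)
  keep <- vapply(st, function(s) {
    wv <- strsplit(substr(subj_str, s, s + k - 1L), "")[[1L]]
    !any(wv == "N" & pv != "N")
  }, logical(1L))
  st[keep]
}

#' Scan a genome for an IUPAC motif
#'
#' Reports every window matching the pattern under IUPAC semantics,
#' including overlapping windows and, for circular genomes, windows that
#' wrap across the origin (counted once).  Minus-strand hits are matches of
#' the reverse-complemented pattern reported in forward-frame coordinates.
#' `N` in the genome never matches a non-N pattern code.
#'
#' @param genome A `genome_seq`.
#' @param motif An `iupac_motif`.
#' @param strand `"both"` (default), `"+"` or `"-"`.
#' @return A data frame with columns `start` (0-based), `end`
#'   (exclusive; may exceed the genome length for wrap-spanning windows),
#'   `strand`, `meth_pos` (forward-frame genome coordinate of the modified
#'   base), `meth_strand` and `pattern`.
#' @export
scan_motif <- function(genome, motif, strand = c("both", "+", "-")) {
  strand <- match.arg(strand)
  stopifnot(inherits(genome, "genome_seq"), inherits(motif, "iupac_motif"))
  L <- genome$length
  k <- motif$length
  if (k > L) stop("motif longer than genome")
  subj_str <- if (genome$circular && k > 1L)
    paste0(genome$seq, substr(genome$seq, 1L, k - 1L)) else genome$seq
  subj_dna <- Biostrings::DNAString(subj_str)
  off <- motif$methylated_offset

  out <- list()
  if (strand %in% c("both", "+")) {
    st0 <- .scan_starts(motif$pattern, subj_str, subj_dna, L) - 1L
    if (length(st0))
      out[["+"]] <- data.frame(
        start = st0, end = st0 + k, strand = "+",
        meth_pos = (st0 + off) %% L, meth_strand = "+",
        pattern = motif$pattern, stringsAsFactors = FALSE)
  }
  if (strand %in% c("both", "-")) {
    rc <- reverse_complement_iupac(motif$pattern)
    st0 <- .scan_starts(rc, subj_str, subj_dna, L) - 1L
    if (length(st0))
      out[["-"]] <- data.frame(
        start = st0, end = st0 + k, strand = "-",
        meth_pos = (st0 + (k - 1L - off)) %% L, meth_strand = "-",
        pattern = motif$pattern, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), meth_pos = integer(0),
                      meth_strand = character(0), pattern = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Census of a complementary motif pair
#'
#' A bipartite recognition motif and its reverse complement form one
#' recognition site seen from the two strands.  It is ambiguous whether a
#' printed motif count refers to forward-strand occurrences of both written
#' patterns or to a both-strand scan deduplicated over the complementary
#' pair, so both conventions are reported side by side.
#'
#' @param genome A `genome_seq`.
#' @param motif An `iupac_motif`; its reverse complement is derived
#'   internally.
#' @return A list with `forward_both_patterns` (count of forward-strand
#'   matches of the pattern plus its reverse complement), `both_strand_all`
#'   (all stranded hits of the single pattern) and
#'   `both_strand_dedup` (unique windows irrespective of strand), plus the
#'   underlying `hits` table.
#' @export
motif_census <- function(genome, motif) {
  hits <- scan_motif(genome, motif, "both")
  list(
    forward_both_patterns = nrow(hits),  # fwd match of pat == minus match of rc
    both_strand_all = nrow(hits),
    both_strand_dedup = length(unique(hits$start)),
    hits = hits
  )
}

#' Base composition of a genome
#'
#' Counts each base on the forward strand and on both strands combined
#' (where the both-strand A count is forward A + forward T, etc.).  The
#' both-strand A+C total equals the genome length minus the N count: every
#' base pair contributes exactly one adenine or one cytosine.
#'
#' @param genome A `genome_seq`.
#' @return A list with `forward` (named counts of A, C, G, T, N),
#'   `both_strand` (named counts of A and C over both strands) and
#'   `a_plus_c` (their sum).
#' @export
base_composition <- function(genome) {
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(genome$seq),
                                     baseOnly = TRUE)
  forward <- c(A = unname(f["A"]), C = unname(f["C"]),
               G = unname(f["G"]), T = unname(f["T"]),
               N = unname(f["other"]))
  both <- c(A = unname(forward["A"] + forward["T"]),
            C = unname(forward["C"] + forward["G"]))
  list(forward = forward, both_strand = both,
       a_plus_c = unname(both["A"] + both["C"]))
}

#' Construct a gene annotation table
#'
#' @param locus_tag Unique gene identifiers.
#' @param start 0-based inclusive start coordinates.
#' @param end 0-based exclusive end coordinates (a wrap-spanning gene on a
#'   circular genome has `end > genome length`, interpreted modularly).
#' @param strand `"+"` or `"-"` per gene.
#' @param product Optional free-text product descriptions.
#' @return A data frame with the four (five) columns above.
#' @export
gene_table <- function(locus_tag, start, end, strand,
                       product = rep("", length(locus_tag))) {
  locus_tag <- as.character(locus_tag)
  start <- as.integer(start); end <- as.integer(end)
  strand <- as.character(strand)
  if (anyDuplicated(locus_tag)) stop("locus_tag values must be unique")
  if (any(start < 0L) || any(end <= start))
    stop("gene intervals must satisfy 0 <= start < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(locus_tag = locus_tag, start = start, end = end,
             strand = strand, product = as.character(product),
             stringsAsFactors = FALSE)
}

#' Read a gene annotation from TSV or GFF3
#'
#' The TSV dialect has a header line and columns `locus_tag`, `start`
#' (0-based), `end` (exclusive), `strand` and optionally `product`.  GFF3
#' input (1-based inclusive coordinates) is parsed with `rtracklayer`; gene
#' or CDS features are used and the `locus_tag` attribute (falling back to
#' `ID`) names each gene.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @return A gene table as from [gene_table()].
#' @export
read_annotation <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  if (format == "tsv") {
    d <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("locus_tag", "start", "end", "strand")
    if (!all(need %in% names(d)))
      stop("annotation TSV must have columns locus_tag, start, end, strand")
    prod <- if ("product" %in% names(d)) d$product else rep("", nrow(d))
    return(gene_table(d$locus_tag, d$start, d$end, d$strand, prod))
  }
  gr <- rtracklayer::import(path, format = "gff3")
  d <- as.data.frame(gr)
  keep <- d$type %in% c("gene", "CDS")
  if (any(keep)) d <- d[keep, , drop = FALSE]
  tags <- if ("locus_tag" %in% names(d) && !all(is.na(d$locus_tag)))
    as.character(d$locus_tag) else as.character(d$ID)
  prod <- if ("product" %in% names(d)) as.character(d$product) else rep("", nrow(d))
  prod[is.na(prod)] <- ""
  gene_table(tags, d$start - 1L, d$end, as.character(d$strand), prod)
}

#' Write a gene annotation as 4-column TSV
#'
#' @param genes A gene table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(genes, path) {
  write.table(genes[, c("locus_tag", "start", "end", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write motif hits as BED6
#'
#' 0-based half-open coordinates; `name` carries the pattern, `score` is 0.
#'
#' @param hits Hit table from [scan_motif()].
#' @param path Output path.
#' @param seqid Chromosome name for column 1.
#' @return `path`, invisibly.
#' @export
write_bed <- function(hits, path, seqid = "chr") {
  bed <- data.frame(chrom = seqid, start = hits$start, end = hits$end,
                    name = hits$pattern, score = 0L, strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
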