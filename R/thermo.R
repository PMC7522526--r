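## Nearest-neighbor duplex stability (dG37) and melting-temperature
## profiling over genome windows.
##
## Parameters are the unified Watson-Crick nearest-neighbor set for 1 M
## NaCl (dH in kcal/mol, dS in cal/(mol K), dG37 in kcal/mol), shipped as a
## versioned plain-text table so an alternative parameter file can be
## supplied and audited.

#' Load a nearest-neighbor parameter set
#'
#' Reads a tab-separated table with columns `name`, `dH`, `dS`, `dG37`
#' holding the 16 dinucleotide stacks plus `init_AT`, `init_GC` (duplex
#' initiation with a terminal A/T or G/C pair) and `sym` (self-complementary
#' symmetry correction).  The complementary-stack symmetry of the table
#' (value of XY equals value of the reverse-complement stack) is validated.
#'
#' @param path Parameter file; default is the unified 1 M NaCl table shipped
#'   with the package.
#' @return A list of class `nn_params` with elements `dH`, `dS`, `dG37`
#'   (named vectors over the 16 stacks), `init_AT`, `init_GC`, `sym` (each a
#'   named numeric of dH, dS, dG37) and `salt_conc`.
#' @export
nn_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nn_unified_1M_NaCl.tsv",
                        package = "methlink")
  d <- read.delim(path, stringsAsFactors = FALSE)
  stacks <- d[!grepl("^(init_|sym)", d$name), , drop = FALSE]
  all16 <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           paste0))
  if (!setequal(stacks$name, all16))
    stop("parameter file must define all 16 dinucleotide stacks")
  pick <- function(col) setNames(stacks[[col]], stacks$name)
  term <- function(nm) {
    row <- d[d$name == nm, , drop = FALSE]
    if (nrow(row) != 1L) stop(sprintf("parameter file must define '%s'", nm))
    c(dH = row$dH, dS = row$dS, dG37 = row$dG37)
  }
  p <- structure(list(dG37 = pick("dG37"), dH = pick("dH"), dS = pick("dS"),
                      init_AT = term("init_AT"), init_GC = term("init_GC"),
                      sym = term("sym"), salt_conc = 1.0),
                 class = "nn_params")
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste0(substr(s, 2, 2), substr(s, 1, 1)))
  for (col in c("dG37", "dH", "dS")) {
    v <- p[[col]]
    if (any(abs(v - v[vapply(names(v), rc, character(1L))]) > 1e-9))
      stop("parameter table violates complementary-stack symmetry")
  }
  p
}

#' Is a sequence self-complementary?
#'
#' @param seq Nucleotide string.
#' @return `TRUE`/`FALSE`.
#' @export
is_self_complementary <- function(seq) {
  seq <- toupper(seq)
  nchar(seq) %% 2L == 0L && seq == reverse_complement_iupac(seq)
}

.stacks_of <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq_len(n - 1L), seq_len(n - 1L) + 1L)
}

.terminal_term <- function(base, params, what) {
  t <- if (base %in% c("A", "T")) params$init_AT else params$init_GC
  unname(t[what])
}

#' Duplex stability of a sequence at 37 degrees C
#'
#' Sums the stack free energies over consecutive dinucleotides and adds the
#' two terminal initiation terms (and the symmetry correction for
#' self-complementary duplexes).  Sequences containing N are rejected here;
#' genomic windows with N content are masked in [window_profile()].
#'
#' @param seq Nucleotide string, length >= 2, no N.
#' @param params An `nn_params` set.
#' @return Free energy in kcal/mol (negative = more stable).
#' @export
duplex_dG37 <- function(seq, params = nn_params()) {
  seq <- toupper(seq)
  if (nchar(seq) < 2L) stop("sequence must have at least 2 bases")
  if (grepl("[^ACGT]", seq))
    stop("sequence must be over {A,C,G,T}; mask windows containing N")
  total <- sum(params$dG37[.stacks_of(seq)]) +
    .terminal_term(substr(seq, 1L, 1L), params, "dG37") +
    .terminal_term(substr(seq, nchar(seq), nchar(seq)), params, "dG37")
  if (is_self_complementary(seq)) total <- total + unname(params$sym["dG37"])
  total
}

#' Nearest-neighbor stability profile over genome windows
#'
#' Tiles the genome with fixed-size windows (non-overlapping by default;
#' pass `step < window` for a sliding profile) and reports the per-stack
#' mean dG37 in each window.  On circular genomes the final window wraps
#' across the origin.  Stacks containing N are excluded from the mean, and
#' windows whose N fraction exceeds `max_n_frac` are masked (`NA`).  Signed
#' dG37 is stored; exporters may negate for "melting energy" plots.
#'
#' @param genome A `genome_seq`.
#' @param params An `nn_params` set.
#' @param window Window size in bp (default 100,000).
#' @param step Step between window starts (default `window`, i.e. tiling).
#' @param max_n_frac Maximum tolerated N fraction per window.
#' @return Data frame with `window_start`, `window_size`, `mean_dG37`,
#'   `gc_frac`, `n_frac` and `masked`.
#' @export
window_profile <- function(genome, params = nn_params(), window = 100000L,
                           step = window, max_n_frac = 0.1) {
  L <- genome$length
  window <- as.integer(window); step <- as.integer(step)
  if (window > L) stop("window larger than genome")
  if (window < 2L || step < 1L) stop("window must be >= 2 and step >= 1")
  starts <- seq.int(0L, L - 1L, by = step)
  if (!genome$circular) starts <- starts[starts + window <= L]
  ext <- if (genome$circular) paste0(genome$seq, substr(genome$seq, 1L, window))
         else genome$seq
  rows <- lapply(starts, function(s0) {
    w <- substr(ext, s0 + 1L, s0 + window)
    chars <- strsplit(w, "")[[1L]]
    n_frac <- mean(chars == "N")
    gc_frac <- mean(chars %in% c("G", "C"))
    if (n_frac > max_n_frac)
      return(data.frame(window_start = s0, window_size = window,
                        mean_dG37 = NA_real_, gc_frac = gc_frac,
                        n_frac = n_frac, masked = TRUE))
    st <- .stacks_of(w)
    ok <- !grepl("N", st, fixed = TRUE)
    data.frame(window_start = s0, window_size = window,
               mean_dG37 = if (any(ok)) mean(params$dG37[st[ok]]) else NA_real_,
               gc_frac = gc_frac, n_frac = n_frac, masked = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nearest-neighbor melting temperature of a duplex
#'
#' `Tm = dH / (dS + R ln(CT / x)) - 273.15`, with total enthalpy/entropy
#' including initiation (and symmetry for self-complementary duplexes),
#' `R = 1.987 cal/(mol K)` and `x = 4` for non-self-complementary duplexes
#' (1 for self-complementary).
#'
#' @param seq Nucleotide string (no N).
#' @param params An `nn_params` set.
#' @param strand_conc Total strand concentration CT in mol/L.
#' @return Melting temperature in degrees C.
#' @export
melting_temperature <- function(seq, params = nn_params(),
                                strand_conc = 1e-4) {
  seq <- toupper(seq)
  if (nchar(seq) < 2L) stop("sequence must have at least 2 bases")
  if (grepl("[^ACGT]", seq)) stop("sequence must be over {A,C,G,T}")
  st <- .stacks_of(seq)
  selfc <- is_self_complementary(seq)
  dH <- sum(params$dH[st]) +
    .terminal_term(substr(seq, 1L, 1L), params, "dH") +
    .terminal_term(substr(seq, nchar(seq), nchar(seq)), params, "dH") +
    if (selfc) unname(params$sym["dH"]) else 0
  dS <- sum(params$dS[st]) +
    .terminal_term(substr(seq, 1L, 1L), params, "dS") +
    .terminal_term(substr(seq, nchar(seq), nchar(seq)), params, "dS") +
    if (selfc) unname(params$sym["dS"]) else 0
  x <- if (selfc) 1 else 4
  denom <- dS + 1.987 * log(strand_conc / x)
  if (denom == 0) stop("undefined melting temperature (zero denominator)")
  dH * 1000 / denom - 273.15
}

#' Write a window profile as bedGraph
#'
#' @param profile Output of [window_profile()].
#' @param path Output path.
#' @param seqid Chromosome name.
#' @param negate Write `-mean_dG37` ("melting energy" convention) instead of
#'   the signed value.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, seqid = "chr", negate = FALSE) {
  v <- profile$mean_dG37
  if (negate) v <- -v
  keep <- !is.na(v)
  d <- data.frame(seqid, profile$window_start[keep],
                  profile$window_start[keep] + profile$window_size[keep],
                  v[keep])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
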