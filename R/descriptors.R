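# Composition-based peptide descriptors. Composition-type values are
# percentages; the descriptor tables (CTD property groups, PCP residue
# classes) ship as CSV resources under inst/extdata so they can be swapped
# for alternative partitions without touching code.

.tables_env <- new.env(parent = emptyenv())

readPackagedTable <- function(file) {
  key <- file
  if (is.null(.tables_env[[key]])) {
    path <- system.file("extdata", file, package = "il2kit", mustWork = TRUE)
    .tables_env[[key]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .tables_env[[key]]
}

ctdGroupTable <- function() readPackagedTable("ctd_groups.csv")
pcpClassTable <- function() readPackagedTable("pcp_classes.csv")

seqToResidues <- function(sequence) {
  r <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(r, AA_ALPHABET20)
  if (length(bad)) stop("non-canonical residue(s): ", paste(bad, collapse = ","))
  r
}

#' Amino-acid composition (AAC)
#'
#' Percentage frequency of each of the 20 canonical residues:
#' `AAC_a = 100 * count(a) / L`. The vector sums to 100.
#'
#' @param sequence a single peptide string.
#' @return named numeric 20-vector (names `AAC_A` .. `AAC_Y`).
#' @examples
#' computeAAC("ACDEFGHIKLMNPQRSTVWY")  # every residue 5
#' @export
computeAAC <- function(sequence) {
  r <- seqToResidues(sequence)
  if (length(r) < 1) stop("empty sequence")
  counts <- table(factor(r, levels = AA_ALPHABET20))
  out <- 100 * as.numeric(counts) / length(r)
  names(out) <- paste0("AAC_", AA_ALPHABET20)
  out
}

DIPEPTIDES <- as.vector(outer(AA_ALPHABET20, AA_ALPHABET20,
                              function(a, b) paste0(a, b)))

#' Dipeptide composition (DPC)
#'
#' Percentage frequency of each of the 400 ordered adjacent residue pairs:
#' `DPC_xy = 100 * count(xy) / (L - 1)`; sums to 100. With
#' `appendLength = TRUE` a 401st entry `LEN` holds the raw residue count
#' (the DPC_LEN hybrid feature set).
#'
#' @inheritParams computeAAC
#' @param appendLength append the peptide length as an extra feature.
#' @return named numeric 400- or 401-vector.
#' @export
computeDPC <- function(sequence, appendLength = FALSE) {
  r <- seqToResidues(sequence)
  L <- length(r)
  if (L < 2) stop("dipeptide composition needs length >= 2")
  pairs <- paste0(r[-L], r[-1])
  counts <- table(factor(pairs, levels = DIPEPTIDES))
  out <- 100 * as.numeric(counts) / (L - 1)
  names(out) <- paste0("DPC_", DIPEPTIDES)
  if (appendLength) out <- c(out, LEN = L)
  out
}

# group index (1..3) per residue for one CTD property
ctdGroupIndex <- function(residues, prop_rows) {
  g <- integer(length(residues))
  for (k in seq_len(nrow(prop_rows))) {
    members <- strsplit(prop_rows$residues[k], "")[[1]]
    g[residues %in% members] <- prop_rows$group[k]
  }
  g
}

#' Composition/transition/distribution (CTD) descriptors
#'
#' Classical CTD over 7 physicochemical properties (hydrophobicity,
#' normalized van der Waals volume, polarity, polarizability, charge,
#' secondary structure, solvent accessibility), each partitioning the 20
#' residues into 3 groups. Per property: 3 group-composition percentages,
#' 3 between-group transition percentages (unordered adjacent pairs crossing
#' groups, over L-1 pairs), and per group the positions (as percent of L) of
#' the first, 25\%, 50\%, 75\% and 100\% occurrence — 0 when the group is
#' absent. Total 7 x 21 = 147 features.
#'
#' @inheritParams computeAAC
#' @return named numeric 147-vector.
#' @export
computeCTD <- function(sequence) {
  r <- seqToResidues(sequence)
  L <- length(r)
  if (L < 2) stop("CTD needs length >= 2")
  tab <- ctdGroupTable()
  props <- unique(tab$property)
  out <- numeric(0)
  for (p in props) {
    rows <- tab[tab$property == p, ]
    g <- ctdGroupIndex(r, rows)
    comp <- 100 * tabulate(g, 3) / L
    names(comp) <- paste0("CTD_", p, "_C", 1:3)
    a <- g[-L]; b <- g[-1]
    lo <- pmin(a, b); hi <- pmax(a, b)
    tr <- c(sum(lo == 1 & hi == 2), sum(lo == 1 & hi == 3),
            sum(lo == 2 & hi == 3))
    tr <- 100 * tr / (L - 1)
    names(tr) <- paste0("CTD_", p, "_T", c("12", "13", "23"))
    dist <- numeric(15)
    dn <- character(15)
    qs <- c(0, 0.25, 0.50, 0.75, 1)
    for (k in 1:3) {
      pos <- which(g == k)
      vals <- if (length(pos) == 0) rep(0, 5) else {
        ii <- pmax(1L, ceiling(qs * length(pos)))
        100 * pos[ii] / L
      }
      dist[(k - 1) * 5 + 1:5] <- vals
      dn[(k - 1) * 5 + 1:5] <- paste0("CTD_", p, "_D", k, "_",
                                      c("first", "25", "50", "75", "100"))
    }
    names(dist) <- dn
    out <- c(out, comp, tr, dist)
  }
  out
}

#' Physicochemical class composition (PCP)
#'
#' Percentage composition over a fixed table of 25 binary residue classes
#' (charged, polar, aliphatic, aromatic, tiny, buried, ...; see
#' `system.file("extdata", "pcp_classes.csv", package = "il2kit")`):
#' `PCP_c = 100 * count(residues in class c) / L`. Classes overlap, so the
#' vector does not sum to 100.
#'
#' @inheritParams computeAAC
#' @return named numeric 25-vector.
#' @export
computePCP <- function(sequence) {
  r <- seqToResidues(sequence)
  if (length(r) < 1) stop("empty sequence")
  tab <- pcpClassTable()
  out <- vapply(seq_len(nrow(tab)), function(k) {
    members <- strsplit(tab$residues[k], "")[[1]]
    100 * sum(r %in% members) / length(r)
  }, numeric(1))
  names(out) <- paste0("PCP_", tab$class)
  out
}

#' Distance distribution of residues (DDR)
#'
#' For each residue type `a`: `DDR_a = 100 * (sum of index gaps between
#' successive occurrences of a) / L`, and 0 when `a` occurs at most once.
#'
#' @inheritParams computeAAC
#' @return named numeric 20-vector.
#' @export
computeDDR <- function(sequence) {
  r <- seqToResidues(sequence)
  L <- length(r)
  if (L < 1) stop("empty sequence")
  out <- vapply(AA_ALPHABET20, function(a) {
    pos <- which(r == a)
    if (length(pos) <= 1) 0 else 100 * sum(diff(pos)) / L
  }, numeric(1))
  names(out) <- paste0("DDR_", AA_ALPHABET20)
  out
}

#' Repetitive residue information (RRI)
#'
#' For each residue type `a`: the sum over maximal runs of `a` of the
#' squared run length, divided by `L`. E.g. `"AAAB"` gives
#' `RRI_A = 3^2 / 4 = 2.25`.
#'
#' @inheritParams computeAAC
#' @return named numeric 20-vector.
#' @export
computeRRI <- function(sequence) {
  r <- seqToResidues(sequence)
  L <- length(r)
  if (L < 1) stop("empty sequence")
  rl <- rle(r)
  out <- vapply(AA_ALPHABET20, function(a) {
    sum(rl$lengths[rl$values == a]^2) / L
  }, numeric(1))
  names(out) <- paste0("RRI_", AA_ALPHABET20)
  out
}

#' Terminal binary profile (AAB)
#'
#' One-hot encoding over the 20 residues at 16 positions: the N-terminal
#' `nTerm` positions (N1..N8) and the C-terminal `cTerm` positions (C1..C8,
#' C8 = last residue). For peptides shorter than `nTerm + cTerm` the two
#' windows overlap (each window is defined independently); positions beyond
#' the sequence are all-zero.
#'
#' @inheritParams computeAAC
#' @param nTerm,cTerm window sizes (default 8 each).
#' @return named numeric binary vector of length `20 * (nTerm + cTerm)`
#'   (320 with defaults).
#' @export
computeAAB <- function(sequence, nTerm = 8L, cTerm = 8L) {
  r <- seqToResidues(sequence)
  L <- length(r)
  out <- numeric(20 * (nTerm + cTerm))
  nm <- character(20 * (nTerm + cTerm))
  res_idx <- match(r, AA_ALPHABET20)
  for (i in seq_len(nTerm)) {
    block <- (i - 1) * 20
    nm[block + 1:20] <- paste0("AAB_N", i, "_", AA_ALPHABET20)
    if (i <= L) out[block + res_idx[i]] <- 1
  }
  for (j in seq_len(cTerm)) {
    block <- (nTerm + j - 1) * 20
    nm[block + 1:20] <- paste0("AAB_C", j, "_", AA_ALPHABET20)
    p <- L - cTerm + j
    if (p >= 1) out[block + res_idx[p]] <- 1
  }
  names(out) <- nm
  out
}

FEATURE_SETS <- c("AAC", "DPC", "DPC_LEN", "CTD", "PCP", "DDR", "RRI", "AAB")

#' Compute a feature matrix for a peptide set
#'
#' Dispatches to the per-sequence descriptor for the requested feature set;
#' rows align with the record order of `x` (no hidden sorting) and carry the
#' record ids as row names. The feature-set tag is stored in the
#' `"featureSet"` attribute.
#'
#' @param x a [PeptideSet-class]
#' @param featureSet one of `"AAC"`, `"DPC"`, `"DPC_LEN"`, `"CTD"`,
#'   `"PCP"`, `"DDR"`, `"RRI"`, `"AAB"`.
#' @return numeric matrix, one row per peptide.
#' @examples
#' ps <- PeptideSet(c(a = "ACDEFGHIKL", b = "LLLLAAAAKK"))
#' dim(computeFeatures(ps, "AAC"))
#' @export
computeFeatures <- function(x, featureSet = c("AAC", "DPC", "DPC_LEN", "CTD",
                                              "PCP", "DDR", "RRI", "AAB")) {
  featureSet <- match.arg(featureSet)
  f <- switch(featureSet,
    AAC = computeAAC,
    DPC = function(s) computeDPC(s, appendLength = FALSE),
    DPC_LEN = function(s) computeDPC(s, appendLength = TRUE),
    CTD = computeCTD,
    PCP = computePCP,
    DDR = computeDDR,
    RRI = computeRRI,
    AAB = computeAAB)
  seqs <- peptideSequences(x)
  if (length(seqs) == 0) stop("empty peptide set")
  rows <- lapply(seqs, f)
  m <- do.call(rbind, rows)
  rownames(m) <- peptideIds(x)
  attr(m, "featureSet") <- featureSet
  m
}

#' Write / read a feature matrix as CSV
#'
#' Round-trips a [computeFeatures()] matrix through CSV with an `id` column
#' and a header row.
#'
#' @param m feature matrix
#' @param path file path
#' @export
writeFeatureCSV <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
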