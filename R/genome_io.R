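# Annotated circular genomes: construction, gene-name normalization,
# functional categories, and circular-coordinate primitives used everywhere
# downstream.
#
# Coordinates are 0-based half-open on the circle. A feature with end <=
# start wraps through the origin (wrap flag set); feature_seq() is the single
# place where the wrap is linearized.

GENE_CATEGORIES <- c("photosynthesis", "atp_synthase", "cytochrome",
                     "ribosomal_protein", "rna_polymerase", "rRNA", "tRNA",
                     "other_conserved", "orf")

#' Construct an annotated genome
#'
#' The universal input object of the package: a circular (or linear)
#' nucleotide sequence plus an ordered table of gene features.
#'
#' @param id accession or label.
#' @param sequence nucleotide string over A,C,G,T,N.
#' @param features data.frame with columns `name`, `gene_type` (one of
#'   protein/rRNA/tRNA), `strand` (+1/-1), `start`, `end` (0-based half-open;
#'   `end <= start` only for origin-spanning features) and optionally
#'   `category`; other columns are preserved.
#' @param circular logical; plastid genomes are circular.
#' @return an object of class `annotated_genome` with elements `id`,
#'   `sequence`, `circular`, `length` and `features` (sorted by `start`, with
#'   derived columns `wrap` and `length_bp`).
#' @export
annotated_genome <- function(id, sequence, features, circular = TRUE) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0L) stop("genome sequence must be non-empty")
  if (is.null(features) || nrow(features) == 0L) {
    features <- data.frame(name = character(0), gene_type = character(0),
                           category = character(0), strand = integer(0),
                           start = integer(0), end = integer(0))
  }
  req <- c("name", "gene_type", "strand", "start", "end")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  if (any(features$start < 0 | features$start >= L)) {
    stop("feature start out of range [0, L)")
  }
  if (!"category" %in% names(features)) {
    features$category <- mapply(classify_gene, features$name, features$gene_type,
                                USE.NAMES = FALSE)
  }
  features$wrap <- features$end <= features$start
  features$length_bp <- ifelse(features$wrap,
                               L - features$start + features$end,
                               features$end - features$start)
  if (any(features$length_bp <= 0 | features$length_bp > L)) {
    stop("feature length must be in (0, L]")
  }
  features <- features[order(features$start, features$end), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(id = id, sequence = sequence, circular = circular,
                 length = L, features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  tab <- table(factor(x$features$gene_type, levels = c("protein", "rRNA", "tRNA")))
  cat(sprintf("<annotated_genome> %s: %s bp, %s, %d features (%d protein, %d rRNA, %d tRNA)\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features), tab[["protein"]], tab[["rRNA"]], tab[["tRNA"]]))
  invisible(x)
}

#' Normalize a raw gene name to the community symbol
#'
#' Case-folds symbols to the organelle-genome convention (`atpI`, `rpl12`,
#' `rbcL`, `rpoC1`); renders tRNAs as one-letter amino-acid code plus
#' anticodon in RNA alphabet, e.g. `trnL(GAG)`, so that isoacceptors remain
#' distinct; and applies a curated synonym table (e.g. "16S ribosomal RNA"
#' -> `rrs`). Unknown names pass through with the generic case fold.
#'
#' @param raw raw gene name or product string. Vectorised.
#' @return normalized symbol(s).
#' @export
#' @examples
#' normalize_gene_name("ATPI")          # "atpI"
#' normalize_gene_name("tRNA-Leu(gag)") # "trnL(GAG)"
#' normalize_gene_name("16S ribosomal RNA") # "rrs"
normalize_gene_name <- function(raw) {
  vapply(raw, normalize_gene_name_one, character(1), USE.NAMES = FALSE)
}

# curated synonym table; keys are matched case-insensitively after trimming
GENE_SYNONYMS <- c(
  "16s ribosomal rna" = "rrs", "16s rrna" = "rrs", "rrn16" = "rrs",
  "rrna-16s" = "rrs", "rrn16s" = "rrs", "rns" = "rrs",
  "23s ribosomal rna" = "rrl", "23s rrna" = "rrl", "rrn23" = "rrl",
  "rrna-23s" = "rrl", "rrn23s" = "rrl", "rnl" = "rrl",
  "5s ribosomal rna" = "rrf", "5s rrna" = "rrf", "rrn5" = "rrf",
  "rrna-5s" = "rrf", "rrn5s" = "rrf", "rrn5.8" = "rrf",
  "rbc" = "rbcL", "tufa elongation factor tu" = "tufA"
)

AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
            Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
            Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
            Tyr = "Y", Val = "V", fMet = "M", Sec = "U")

normalize_gene_name_one <- function(raw) {
  if (is.na(raw) || !nzchar(trimws(raw))) stop("gene name must be non-empty")
  x <- trimws(raw)
  key <- tolower(x)
  if (key %in% names(GENE_SYNONYMS)) return(unname(GENE_SYNONYMS[[key]]))

  # tRNA forms: trnL(GAG), trnL-GAG, tRNA-Leu(gag), tRNA-Leu-GAG, trnl_gag
  m <- regmatches(x, regexec(
    "^t[Rr]?[Nn][Aa]?[-_ ]?([A-Za-z]{1,4})[-_ (]+([ACGTUacgtu]{3})\\)?$", x))[[1L]]
  if (length(m) == 3L) {
    aa <- m[2L]
    aa1 <- if (nchar(aa) == 1L) toupper(aa) else {
      unname(AA3TO1[paste0(toupper(substr(aa, 1, 1)), tolower(substr(aa, 2, nchar(aa))))])
    }
    if (length(aa1) == 1L && !is.na(aa1)) {
      anticodon <- chartr("T", "U", toupper(m[3L]))
      return(sprintf("trn%s(%s)", aa1, anticodon))
    }
  }

  # generic symbol: 3-letter lowercase prefix, suffix letters upper-cased
  # (atpi -> atpI, rpoc1 -> rpoC1, rpl12 -> rpl12, ycf3 -> ycf3)
  m <- regmatches(x, regexec("^([A-Za-z]{3})([A-Za-z0-9]{0,4})$", x))[[1L]]
  if (length(m) == 3L) {
    prefix <- tolower(m[2L])
    suffix <- m[3L]
    if (prefix %in% c("orf", "ycf", "rrs", "rrl", "rrf")) {
      return(paste0(prefix, tolower(suffix)))
    }
    chs <- strsplit(suffix, "", fixed = TRUE)[[1L]]
    chs <- ifelse(grepl("[A-Za-z]", chs), toupper(chs), chs)
    return(paste0(prefix, paste(chs, collapse = "")))
  }
  x  # unknown shape: passed through unchanged
}

#' Functional category of a gene
#'
#' Assigns one of nine functional groups used for plastid gene maps:
#' photosynthesis (photosystems, rbcL, chlorophyll biosynthesis), ATP
#' synthase, cytochrome (b6/f complex and c-type biogenesis), ribosomal
#' protein, RNA polymerase, rRNA, tRNA, other conserved, or ORF/unknown.
#'
#' @param name normalized gene symbol.
#' @param gene_type one of protein/rRNA/tRNA (used as a fallback).
#' @return category string.
#' @export
classify_gene <- function(name, gene_type = "protein") {
  if (gene_type == "tRNA" || grepl("^trn", name)) return("tRNA")
  if (gene_type == "rRNA" || name %in% c("rrs", "rrl", "rrf")) return("rRNA")
  if (grepl("^(psa|psb|rbc|chl)", name)) return("photosynthesis")
  if (grepl("^atp", name)) return("atp_synthase")
  if (grepl("^(pet|ccs)", name)) return("cytochrome")
  if (grepl("^(rps|rpl)", name)) return("ribosomal_protein")
  if (grepl("^rpo", name)) return("rna_polymerase")
  if (grepl("^orf", name)) return("orf")
  "other_conserved"
}

# Sequence of one feature row, read 5'->3' on its own strand.
feature_seq <- function(genome, feature) {
  s <- circular_substr(genome$sequence, feature$start, feature$end)
  if (feature$strand < 0) revcomp(s) else s
}

#' Rotate a circular genome by k bp
#'
#' Moves the origin so that old position `k` becomes position 0. No feature
#' length and no downstream statistic changes under rotation.
#'
#' @param genome an `annotated_genome`.
#' @param k offset in bp.
#' @return rotated `annotated_genome`.
#' @export
rotate_genome <- function(genome, k) {
  L <- genome$length
  k <- ((k %% L) + L) %% L
  if (!genome$circular) stop("cannot rotate a linear genome")
  if (k == 0L) return(genome)
  seq2 <- paste0(substr(genome$sequence, k + 1L, L), substr(genome$sequence, 1L, k))
  f <- genome$features
  f$start <- (f$start - k) %% L
  f$end_excl <- (f$end - k) %% L
  f$end <- ifelse(f$end_excl == 0L, L, f$end_excl)
  f$end_excl <- NULL
  annotated_genome(genome$id, seq2, f[, setdiff(names(f), c("wrap", "length_bp"))],
                   circular = genome$circular)
}

#' Reflect a genome (reverse complement the whole circle)
#' @param genome an `annotated_genome`.
#' @return reflected `annotated_genome`; gene order reverses and strands flip.
#' @export
reflect_genome <- function(genome) {
  L <- genome$length
  f <- genome$features
  old_start <- f$start
  old_end <- f$end
  f$start <- (L - old_end) %% L
  f$end <- ifelse((L - old_start) %% L == 0L, L, (L - old_start) %% L)
  f$strand <- -f$strand
  annotated_genome(genome$id, revcomp(genome$sequence),
                   f[, setdiff(names(f), c("wrap", "length_bp"))],
                   circular = genome$circular)
}

#' Extract a gene's coding sequence and its 5' upstream window
#'
#' The upstream window is the `upstream_bp` genomic neighbours 5' of the
#' start codon on the gene's own strand, wrapping through the origin when
#' needed. The window is returned even if it overlaps another annotated
#' gene; the overlap is flagged.
#'
#' @param genome an `annotated_genome`.
#' @param gene normalized gene name (first occurrence used if duplicated).
#' @param upstream_bp window size in bp (default 50, the conventional 5'UTR
#'   proxy for these genomes).
#' @return list with `cds`, `upstream`, and `upstream_overlaps` (TRUE when
#'   the window enters another annotated gene).
#' @export
extract_cds_and_upstream <- function(genome, gene, upstream_bp = 50L) {
  stopifnot(upstream_bp >= 0L)
  idx <- which(genome$features$name == gene)
  if (length(idx) == 0L) stop("gene not found: ", gene)
  ft <- genome$features[idx[1L], ]
  L <- genome$length
  cds <- feature_seq(genome, ft)
  if (upstream_bp == 0L) {
    return(list(cds = cds, upstream = "", upstream_overlaps = FALSE))
  }
  if (ft$strand >= 0) {
    u_start <- (ft$start - upstream_bp) %% L
    u_end <- ft$start
    if (u_end == 0L) u_end <- L
    up <- circular_substr(genome$sequence, u_start, u_end)
  } else {
    u_start <- ft$end %% L
    u_end <- (ft$end + upstream_bp) %% L
    if (u_end == 0L) u_end <- L
    up <- revcomp(circular_substr(genome$sequence, u_start, u_end))
  }
  covered <- coverage_mask(genome)
  win <- if (u_end > u_start) seq(u_start + 1L, u_end) else c(seq(u_start + 1L, L), seq_len(u_end))
  self <- if (ft$wrap) c(seq(ft$start + 1L, L), seq_len(ft$end)) else seq(ft$start + 1L, ft$end)
  overlaps <- any(covered[setdiff(win, self)])
  list(cds = cds, upstream = up, upstream_overlaps = overlaps)
}

# logical vector of length L: position covered by >= 1 feature (1-based index)
coverage_mask <- function(genome) {
  L <- genome$length
  mask <- logical(L)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    if (f$wrap[i]) {
      mask[seq(f$start[i] + 1L, L)] <- TRUE
      if (f$end[i] >= 1L) mask[seq_len(f$end[i])] <- TRUE
    } else {
      mask[seq(f$start[i] + 1L, f$end[i])] <- TRUE
    }
  }
  mask
}

#' Write a per-genome feature table
#' @param genome an `annotated_genome`.
#' @param path output TSV path.
#' @return the feature data.frame, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  f <- genome$features
  utils::write.table(f, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(f)
}
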