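# Minimal GenBank flat-file reader/writer for annotated circular genomes.
# Covers the subset of the format these analyses consume: LOCUS length and
# topology, gene/CDS/tRNA/rRNA features with complement() and origin-spanning
# join() locations, /gene and /product qualifiers, and the ORIGIN block.

#' Read a GenBank flat file into an annotated genome
#'
#' Every gene/CDS/rRNA/tRNA feature becomes one gene record; a CDS (or
#' tRNA/rRNA) and its enclosing `gene` feature are merged. Names are
#' normalized with [normalize_gene_name()]; a feature without any gene or
#' product qualifier is recorded as an ORF with a synthesized name, with a
#' warning. Origin-spanning `join()` locations are resolved to the internal
#' wrap rule (start > end).
#'
#' @param path GenBank flat-file path.
#' @return an [annotated_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank file (no LOCUS line): ", path)
  circular <- grepl("circular", locus[1L], ignore.case = TRUE)
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1L])), "\\s+")[[1L]][1L]
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc) > 0L) {
    a <- strsplit(trimws(sub("^ACCESSION", "", acc[1L])), "\\s+")[[1L]][1L]
    if (!is.na(a) && nzchar(a)) id <- a
  }

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("GenBank record has no ORIGIN sequence: ", path)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[seq(ori[1L] + 1L, endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) stop("GenBank record has an empty sequence: ", path)

  feat_start <- grep("^FEATURES", lines)
  feats <- list()
  if (length(feat_start) > 0L) {
    block <- lines[seq(feat_start[1L] + 1L, ori[1L] - 1L)]
    feats <- parse_feature_block(block)
  }
  features <- assemble_features(feats, nchar(sequence))
  annotated_genome(id, sequence, features, circular = circular)
}

# Split the FEATURES block into (type, location, qualifiers) records.
parse_feature_block <- function(block) {
  recs <- list()
  cur <- NULL
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {                       # new feature header
      if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
      parts <- strsplit(trimws(ln), "\\s+")[[1L]]
      cur <- list(type = parts[1L],
                  location = paste(parts[-1L], collapse = ""),
                  quals = character(0), in_location = TRUE)
    } else if (!is.null(cur) && grepl("^ {21}", ln)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
        cur$in_location <- FALSE
      } else if (isTRUE(cur$in_location)) {            # continued location
        cur$location <- paste0(cur$location, txt)
      } else if (length(cur$quals) > 0L) {             # continued qualifier
        cur$quals[length(cur$quals)] <- paste(cur$quals[length(cur$quals)], txt)
      }
    }
  }
  if (!is.null(cur)) recs[[length(recs) + 1L]] <- cur
  recs
}

# "complement(join(100..200,1..50))" -> list(start, end, strand, wrap)
# in 0-based half-open coordinates on a circle of length L.
parse_location <- function(loc, L) {
  strand <- 1L
  x <- loc
  if (grepl("^complement\\(", x)) {
    strand <- -1L
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  x <- sub("^join\\((.*)\\)$", "\\1", x)
  x <- gsub("[<>]", "", x)
  segs <- strsplit(x, ",", fixed = TRUE)[[1L]]
  m <- regmatches(segs, regexec("^([0-9]+)\\.\\.([0-9]+)$", segs))
  single <- regmatches(segs, regexec("^([0-9]+)$", segs))
  ab <- t(vapply(seq_along(segs), function(i) {
    if (length(m[[i]]) == 3L) as.integer(m[[i]][2:3])
    else if (length(single[[i]]) == 2L) rep(as.integer(single[[i]][2L]), 2L)
    else stop("unparseable GenBank location: ", loc)
  }, integer(2)))
  if (nrow(ab) == 1L) {
    list(start = ab[1, 1] - 1L, end = ab[1, 2], strand = strand, wrap = FALSE)
  } else if (nrow(ab) == 2L && ab[1, 2] == L && ab[2, 1] == 1L) {
    # origin-spanning join(a..L, 1..b)
    list(start = ab[1, 1] - 1L, end = ab[2, 2], strand = strand, wrap = TRUE)
  } else {
    # multi-exon joins are collapsed to their outer span (no introns in the
    # genomes this package targets); flagged via attribute for the caller
    list(start = ab[1, 1] - 1L, end = ab[nrow(ab), 2], strand = strand,
         wrap = FALSE, multi = TRUE)
  }
}

get_qual <- function(quals, key) {
  hit <- grep(paste0("^/", key, "="), quals, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  gsub("^\"|\"$", "", sub(paste0("^/", key, "="), "", hit[1L]))
}

# Merge gene/CDS/tRNA/rRNA records into one feature table.
assemble_features <- function(recs, L) {
  keep <- c("gene", "CDS", "tRNA", "rRNA")
  recs <- Filter(function(r) r$type %in% keep, recs)
  if (length(recs) == 0L) {
    return(data.frame(name = character(0), gene_type = character(0),
                      strand = integer(0), start = integer(0), end = integer(0)))
  }
  rows <- lapply(recs, function(r) {
    loc <- parse_location(r$location, L)
    nm <- get_qual(r$quals, "gene")
    if (is.na(nm)) nm <- get_qual(r$quals, "product")
    if (is.na(nm)) nm <- get_qual(r$quals, "locus_tag")
    data.frame(type = r$type, raw_name = nm, strand = loc$strand,
               start = loc$start, end = loc$end, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  typed <- tab[tab$type != "gene", , drop = FALSE]
  genes <- tab[tab$type == "gene", , drop = FALSE]

  # inherit the gene qualifier from an enclosing gene record with same span
  key <- function(d) paste(d$start, d$end, d$strand)
  gn <- stats::setNames(genes$raw_name, key(genes))
  miss <- is.na(typed$raw_name) & key(typed) %in% names(gn)
  typed$raw_name[miss] <- gn[key(typed)[miss]]

  # gene records with no typed child become protein features (annotation
  # styles that omit the CDS line)
  orphan <- genes[!(key(genes) %in% key(typed)), , drop = FALSE]
  if (nrow(orphan) > 0L) {
    orphan$type <- "CDS"
    typed <- rbind(typed, orphan)
  }

  anon <- is.na(typed$raw_name)
  if (any(anon)) {
    warning(sum(anon), " feature(s) without gene/product qualifier recorded as ORFs")
    typed$raw_name[anon] <- sprintf("orf%d", typed$start[anon] + 1L)
  }
  gene_type <- c(CDS = "protein", tRNA = "tRNA", rRNA = "rRNA")[typed$type]
  data.frame(name = normalize_gene_name(typed$raw_name),
             gene_type = unname(gene_type),
             strand = typed$strand, start = typed$start, end = typed$end,
             stringsAsFactors = FALSE)
}

#' Write an annotated genome as a GenBank flat file
#'
#' Emits LOCUS/ACCESSION headers, paired `gene` + typed (CDS/tRNA/rRNA)
#' features with 1-based inclusive locations (origin-spanning features as
#' `join(a..L,1..b)`), and the ORIGIN sequence block. [read_genbank()] on the
#' output reproduces the genome.
#'
#' @param genome an [annotated_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  L <- genome$length
  con <- file(path, "w")
  on.exit(close(con))
  topo <- if (genome$circular) "circular" else "linear"
  wl <- function(...) writeLines(..., con = con)
  wl(sprintf("LOCUS       %-17s %d bp    DNA     %s PLN 01-JAN-2000",
             genome$id, L, topo))
  wl(sprintf("DEFINITION  %s, synthetic or re-exported plastid genome.", genome$id))
  wl(sprintf("ACCESSION   %s", genome$id))
  wl("FEATURES             Location/Qualifiers")
  wl(sprintf("     source          1..%d", L))
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    loc <- if (f$wrap[i]) {
      sprintf("join(%d..%d,1..%d)", f$start[i] + 1L, L, f$end[i])
    } else {
      sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    }
    if (f$strand[i] < 0) loc <- sprintf("complement(%s)", loc)
    typed <- c(protein = "CDS", tRNA = "tRNA", rRNA = "rRNA")[[f$gene_type[i]]]
    wl(sprintf("     %-15s %s", "gene", loc))
    wl(sprintf("                     /gene=\"%s\"", f$name[i]))
    wl(sprintf("     %-15s %s", typed, loc))
    wl(sprintf("                     /gene=\"%s\"", f$name[i]))
    if (typed == "CDS") {
      wl("                     /codon_start=1")
      wl("                     /transl_table=11")
    }
  }
  wl("ORIGIN")
  s <- tolower(genome$sequence)
  starts <- seq(1L, L, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, L))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    wl(sprintf("%9d %s", st, paste(tens, collapse = " ")))
  }
  wl("//")
  invisible(path)
}
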