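# File formats: FASTA and GFF3 go through Biostrings / rtracklayer; MGF is a
# small line-oriented text format with no installed R parser, so it is read
# and written here directly. GFF3 on disk is 1-based closed; all internal
# coordinates are 0-based half-open.

#' Read a genome (FASTA) together with its annotations (GFF3)
#'
#' Features of type `lanM` in the GFF3 mark the lanthipeptide synthetase loci
#' that anchor precursor mining. Coordinates are converted from the 1-based
#' closed convention of GFF3 to the package's internal 0-based half-open
#' convention.
#'
#' @param fasta_path path to a (multi-)FASTA file.
#' @param gff_path path to a GFF3 file; the `type` column carries the
#'   `lanM` marker and attributes preserve the feature `ID`.
#' @return object of class `genome_record`: list with `seqs` (named character
#'   vector of contig sequences) and `features` (data.frame with columns
#'   feature_id, contig, start, end, strand, type, attributes).
#' @export
read_genome <- function(fasta_path, gff_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  dna <- Biostrings::readDNAStringSet(fasta_path)
  names(dna) <- sub("\\s.*$", "", names(dna))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  ids <- if ("ID" %in% colnames(md)) as.character(md$ID) else
    paste0("feature", seq_along(gr))
  ids[is.na(ids)] <- paste0("feature", which(is.na(ids)))
  attrs <- if ("methyltransferase" %in% colnames(md))
    as.character(md$methyltransferase) else rep(NA_character_, length(gr))
  feats <- data.frame(
    feature_id = ids,
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    methyltransferase = attrs,
    stringsAsFactors = FALSE
  )
  genome_record(seqs = stats::setNames(as.character(dna), names(dna)),
                features = feats)
}

#' Construct a genome record from in-memory data
#'
#' @param seqs named character vector, contig id -> DNA sequence (A,C,G,T,N).
#' @param features data.frame with columns feature_id, contig, start, end
#'   (0-based half-open), strand (`+`/`-`), type; optional column
#'   `methyltransferase`.
#' @return `genome_record`.
#' @export
genome_record <- function(seqs, features) {
  stopifnot(is.character(seqs), length(names(seqs)) == length(seqs))
  need <- c("feature_id", "contig", "start", "end", "strand", "type")
  if (!all(need %in% names(features))) {
    stop("features must have columns: ", paste(need, collapse = ", "))
  }
  if (!all(features$contig %in% names(seqs))) {
    stop("feature contig not present in sequences")
  }
  lens <- nchar(seqs)[features$contig]
  if (any(features$start < 0) || any(features$end > lens) ||
      any(features$start >= features$end)) {
    stop("feature coordinates out of contig bounds")
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'")
  }
  if (!"methyltransferase" %in% names(features)) {
    features$methyltransferase <- NA_character_
  }
  structure(list(seqs = seqs, features = features), class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", length(x$seqs), " contig(s), ",
      nrow(x$features), " feature(s), ",
      sum(x$features$type == "lanM"), " lanM\n", sep = "")
  invisible(x)
}

#' Write a genome record to FASTA + GFF3
#'
#' Internal 0-based half-open coordinates are converted back to the 1-based
#' closed GFF3 convention.
#'
#' @param genome `genome_record`.
#' @param fasta_path,gff_path output paths.
#' @return invisibly, the two paths.
#' @export
write_genome <- function(genome, fasta_path, gff_path) {
  stopifnot(inherits(genome, "genome_record"))
  dna <- Biostrings::DNAStringSet(genome$seqs)
  Biostrings::writeXStringSet(dna, fasta_path)
  f <- genome$features
  gr <- GenomicRanges::GRanges(
    seqnames = f$contig,
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand
  )
  S4Vectors::mcols(gr)$type <- f$type
  S4Vectors::mcols(gr)$ID <- f$feature_id
  S4Vectors::mcols(gr)$source <- "lanmine"
  if (any(!is.na(f$methyltransferase))) {
    S4Vectors::mcols(gr)$methyltransferase <- f$methyltransferase
  }
  rtracklayer::export(gr, gff_path, format = "gff3")
  invisible(c(fasta_path, gff_path))
}

# ---- MGF ---------------------------------------------------------------

#' Read spectra from a Mascot Generic Format (MGF) file
#'
#' Honors TITLE, PEPMASS (first number = precursor m/z), CHARGE (e.g. `2+`)
#' and RTINSECONDS headers; peak lines are whitespace-separated m/z
#' \[intensity\] pairs.
#'
#' @param path MGF file path.
#' @return list of spectra; each spectrum is a list with `title`, `pepmass`,
#'   `charge` (integer or NA), and `peaks` (data.frame mz, intensity).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path)
  spectra <- list()
  in_block <- FALSE
  cur <- NULL
  for (ln_i in seq_along(lines)) {
    ln <- trimws(lines[ln_i])
    if (ln == "" || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("malformed MGF at line ", ln_i, ": nested BEGIN IONS")
      in_block <- TRUE
      cur <- list(title = NA_character_, pepmass = NA_real_,
                  charge = NA_integer_, mz = numeric(), intensity = numeric())
      next
    }
    if (ln == "END IONS") {
      if (!in_block) stop("malformed MGF at line ", ln_i, ": stray END IONS")
      cur$peaks <- data.frame(mz = cur$mz, intensity = cur$intensity)
      cur$mz <- cur$intensity <- NULL
      spectra[[length(spectra) + 1L]] <- cur
      in_block <- FALSE
      next
    }
    if (!in_block) next
    if (grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "TITLE") cur$title <- val
      if (key == "PEPMASS") {
        cur$pepmass <- as.numeric(strsplit(trimws(val), "\\s+")[[1]][1])
      }
      if (key == "CHARGE") {
        cur$charge <- as.integer(gsub("[^0-9]", "", val))
      }
      next
    }
    parts <- strsplit(ln, "\\s+")[[1]]
    mz <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(mz)) stop("malformed MGF peak line ", ln_i, ": '", ln, "'")
    it <- if (length(parts) >= 2) suppressWarnings(as.numeric(parts[2])) else 1
    cur$mz <- c(cur$mz, mz)
    cur$intensity <- c(cur$intensity, if (is.na(it)) 1 else it)
  }
  if (in_block) stop("malformed MGF: unterminated BEGIN IONS block")
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra list of spectra as returned by [read_mgf()] (fields
#'   `title`, `pepmass`, `charge`, `peaks`).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    if (!is.null(sp$title) && !is.na(sp$title)) {
      writeLines(paste0("TITLE=", sp$title), con)
    }
    if (!is.null(sp$pepmass) && !is.na(sp$pepmass)) {
      writeLines(sprintf("PEPMASS=%.6f", sp$pepmass), con)
    }
    if (!is.null(sp$charge) && !is.na(sp$charge)) {
      writeLines(sprintf("CHARGE=%d+", sp$charge), con)
    }
    pk <- sp$peaks
    if (!is.null(pk) && nrow(pk)) {
      writeLines(sprintf("%.6f %.4f", pk$mz, pk$intensity), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Read an MS1 peak list
#'
#' Accepts either a two/three-column TSV (columns `mz`, optional `intensity`,
#' optional `z`) or an MGF file in which each BEGIN IONS block's PEPMASS and
#' CHARGE describe one precursor peak.
#'
#' @param path file path (`.tsv`/`.txt` or `.mgf`).
#' @return data.frame with columns mz, intensity, z (z may be NA).
#' @export
read_ms1_peaks <- function(path) {
  if (!file.exists(path)) stop("peak list not found: ", path)
  if (grepl("\\.mgf$", path, ignore.case = TRUE)) {
    sp <- read_mgf(path)
    return(data.frame(
      mz = vapply(sp, function(s) s$pepmass, numeric(1)),
      intensity = vapply(sp, function(s)
        if (nrow(s$peaks)) max(s$peaks$intensity) else 1, numeric(1)),
      z = vapply(sp, function(s) as.integer(s$charge), integer(1))
    ))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(tab)) stop("peak TSV must have an 'mz' column")
  data.frame(
    mz = as.numeric(tab$mz),
    intensity = if ("intensity" %in% names(tab)) as.numeric(tab$intensity) else 1,
    z = if ("z" %in% names(tab)) as.integer(tab$z) else NA_integer_
  )
}
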