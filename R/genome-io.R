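#' @include methods.R
NULL

#' Read genomes from a FASTA file
#'
#' Reads one [Genome-class] per FASTA record. Lowercase bases are
#' uppercased; the header token before the first whitespace becomes the
#' record id. Characters outside \{A,C,G,T,N\} — including U — are
#' rejected, as are duplicate ids and empty files.
#'
#' @param path Path to a FASTA file.
#' @param circular Logical; topology assigned to every record (bacterial
#'   chromosomes and plasmids are circular by default).
#' @return A named list of [Genome-class] objects.
#' @seealso [writeFasta()], [scanGenome()]
#' @export
readFasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genomes <- lapply(seq_along(set), function(i)
    newGenome(ids[i], as.character(set[[i]]), circular = circular))
  names(genomes) <- ids
  genomes
}

#' Write genomes to a FASTA file
#'
#' @param genomes A [Genome-class] or list of them.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeFasta <- function(genomes, path) {
  if (is(genomes, "Genome")) genomes <- list(genomes)
  set <- Biostrings::DNAStringSet(lapply(genomes, genomeSeq))
  names(set) <- vapply(genomes, genomeId, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a feature annotation from GFF3 or BED
#'
#' Parses gene/ORF features into a data frame with 0-based half-open
#' coordinates regardless of the file dialect: GFF3 (1-based inclusive)
#' start/end are converted as start-1/end, BED is taken as-is. GFF3 types
#' `gene`, `CDS` and `ORF` are classified as kind "ORF", everything else as
#' "other"; BED features are assumed to be ORFs.
#'
#' @param path Path to the annotation file.
#' @param dialect Either "gff3" or "bed".
#' @param genome Optional [Genome-class]; when supplied, coordinates beyond
#'   the genome length are an error.
#' @return A data frame with columns `genome_id`, `start`, `end` (0-based
#'   half-open), `strand`, `kind`, `name`.
#' @seealso [writeAnnotation()], [classifySites()]
#' @export
readAnnotation <- function(path, dialect = c("gff3", "bed"), genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = dialect)
  kind <- if (dialect == "gff3") {
    type <- as.character(gr$type)
    ifelse(type %in% c("gene", "CDS", "ORF"), "ORF", "other")
  } else rep("ORF", length(gr))
  name <- if (dialect == "gff3") {
    nm <- if (!is.null(gr$Name)) as.character(gr$Name) else
      if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
    ifelse(is.na(nm), "", nm)
  } else if (!is.null(gr$name)) as.character(gr$name) else rep("", length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  feats <- data.frame(
    genome_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand, kind = kind, name = name,
    stringsAsFactors = FALSE)
  if (any(feats$end <= feats$start))
    stop("annotation '", path, "' contains features with end <= start")
  if (!is.null(genome)) {
    L <- genomeLength(genome)
    bad <- feats$genome_id == genomeId(genome) & feats$end > L
    if (any(bad))
      stop("feature coordinates beyond genome length ", L, " in '", path,
           "' (first offender: row ", which(bad)[1L], ")")
  }
  feats
}

#' Write a feature annotation to GFF3 or BED
#'
#' Inverse of [readAnnotation()]: internal 0-based half-open coordinates
#' are converted to the dialect's convention at the file boundary, so a
#' write/read cycle is the identity on `genome_id`, `start`, `end`,
#' `strand`, `kind` and `name`.
#'
#' @param features Data frame as returned by [readAnnotation()].
#' @param path Output path.
#' @param dialect Either "gff3" or "bed".
#' @return Invisibly, `path`.
#' @export
writeAnnotation <- function(features, path, dialect = c("gff3", "bed")) {
  dialect <- match.arg(dialect)
  gr <- GenomicRanges::GRanges(
    seqnames = features$genome_id,
    ranges = IRanges::IRanges(start = features$start + 1L,
                              end = features$end),
    strand = features$strand)
  if (dialect == "gff3") {
    gr$type <- ifelse(features$kind == "ORF", "gene", "region")
    gr$source <- "MethylSites"
    gr$Name <- features$name
    gr$ID <- ifelse(nzchar(features$name), features$name,
                    paste0("feat", seq_along(gr)))
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- features$name
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read a TSS table from TSV
#'
#' The file holds one TSS per row with columns `position` (1-based),
#' `strand` ("+"/"-") and optionally `source`; a header line is detected by
#' its leading `position` token and is optional. Positions are stored
#' 0-based in the returned collection.
#'
#' @param path Path to the TSV file.
#' @param source Label for the collection; defaults to the `source` column
#'   if present, else the file stem.
#' @param genomeId Genome the sites live on (default: the file stem).
#' @return A [TSSCollection-class].
#' @seealso [writeTssTable()], [runPermutation()]
#' @export
readTssTable <- function(path, source = NULL, genomeId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  stem <- tools::file_path_sans_ext(basename(path))
  first <- readLines(path, n = 1L)
  hasHeader <- length(first) > 0L && grepl("^position(\t|$)", first)
  if (length(readLines(path)) == 0L ||
      (hasHeader && length(readLines(path)) == 1L)) {
    return(newTssCollection(genomeId %||% stem, integer(0), character(0),
                            source %||% stem))
  }
  tab <- utils::read.delim(path, header = hasHeader,
                           stringsAsFactors = FALSE)
  if (!hasHeader)
    names(tab) <- c("position", "strand", "source")[seq_len(ncol(tab))]
  if (!all(c("position", "strand") %in% names(tab)))
    stop("TSS table '", path, "' must have columns position and strand")
  if (any(is.na(tab$position)) || any(tab$position < 1))
    stop("TSS positions must be 1-based (>= 1) in '", path, "'")
  if (!all(tab$strand %in% c("+", "-")))
    stop("TSS strands must be '+' or '-' in '", path, "'")
  if (is.null(source))
    source <- if ("source" %in% names(tab) && nrow(tab) > 0L)
      as.character(tab$source[1L]) else stem
  newTssCollection(genomeId %||% stem, as.integer(tab$position) - 1L,
                   tab$strand, source)
}

#' Write a TSS collection to TSV
#'
#' Positions are written 1-based with a `position\\tstrand\\tsource` header.
#'
#' @param tss A [TSSCollection-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeTssTable <- function(tss, path) {
  tab <- data.frame(position = tssPositions(tss) + 1L,
                    strand = tssStrands(tss),
                    source = tssSource(tss), stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write motif sites to BED6
#'
#' One line per duplex site (chrom, start, end, name, score 0, strand). A
#' site wrapping the circular origin is written as two lines sharing a
#' name with `/1` and `/2` suffixes.
#'
#' @param sites Site data frame from [scanGenome()].
#' @param path Output path.
#' @param L Genome length; required to split origin-wrapping sites.
#' @return Invisibly, `path`.
#' @export
writeSitesBed <- function(sites, path, L = NULL) {
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    nm <- paste0(s$motif_label, "_", s$start)
    stop0 <- s$start + s$span
    if (!is.null(L) && stop0 > L) {
      data.frame(chrom = s$genome_id,
                 start = c(s$start, 0L), end = c(L, stop0 - L),
                 name = paste0(nm, c("/1", "/2")), score = 0L,
                 strand = s$orientation, stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = s$genome_id, start = s$start, end = stop0,
                 name = nm, score = 0L, strand = s$orientation,
                 stringsAsFactors = FALSE)
    }
  })
  bed <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(bed))
    bed <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
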