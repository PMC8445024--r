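#' @import data.table
#' @importFrom methods is
#' @importFrom stats optim rnorm rpois runif rbinom sd quantile p.adjust
#'   pchisq setNames complete.cases nls coef median mad residuals cor
#'   rgamma rmultinom
#' @importFrom utils head tail
NULL

# Internal coordinate convention: 1-based, closed intervals (GRanges native).
# BED input/output is converted at the boundary (BED start = pos - 1).

DNA_BASES <- c("A", "C", "G", "T")

#' Read a genome FASTA into a DNAStringSet
#'
#' Contig names are taken up to the first whitespace. The alphabet is
#' restricted to A/C/G/T/N; anything else is an error.
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  gen <- Biostrings::readDNAStringSet(path)
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (anyDuplicated(names(gen))) stop("duplicate contig names in ", path)
  freq <- Biostrings::alphabetFrequency(gen, baseOnly = TRUE)
  bad <- freq[, "other"] > 0
  if (any(bad)) {
    stop("contig ", names(gen)[bad][1], " contains letters outside {A,C,G,T,N}")
  }
  gen
}

#' Write a genome to FASTA
#' @param genome named DNAStringSet or named character vector.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

genome_lengths <- function(genome) {
  if (is.character(genome)) return(setNames(nchar(genome), names(genome)))
  setNames(Biostrings::width(genome), names(genome))
}

genome_as_character <- function(genome) {
  if (is.character(genome)) return(genome)
  setNames(as.character(genome), names(genome))
}

#' Construct a gene annotation object
#'
#' A light container holding gene spans and per-gene exon and 3'UTR
#' intervals. Introns are derived as the within-gene complement of the
#' exons, so they are always consistent with the exon structure.
#'
#' @param genes `GRanges` with metadata columns `gene_id` and optionally
#'   `gene_name`; one range per gene.
#' @param exons `GRangesList` (or list of `GRanges`) named by gene id.
#' @param utr3 optional `GRangesList` named by gene id with 3'UTR intervals.
#' @return An object of class `cs_annotation` with elements `genes`,
#'   `exons`, `introns`, `utr3`.
#' @export
gene_annotation <- function(genes, exons, utr3 = NULL) {
  stopifnot(is(genes, "GRanges"), !is.null(genes$gene_id))
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  if (is.list(exons)) exons <- GenomicRanges::GRangesList(exons)
  if (!all(names(exons) %in% genes$gene_id)) {
    stop("exon list contains unknown gene ids")
  }
  nex <- S4Vectors::elementNROWS(exons)
  if (any(nex == 0)) stop("gene with zero exons: ", names(exons)[nex == 0][1])
  missing_ex <- setdiff(genes$gene_id, names(exons))
  if (length(missing_ex)) stop("gene with zero exons: ", missing_ex[1])
  gspan <- setNames(GenomicRanges::granges(genes), genes$gene_id)
  introns <- GenomicRanges::psetdiff(gspan[names(exons)],
                                     GenomicRanges::reduce(exons))
  if (!is.null(utr3)) {
    if (is.list(utr3)) utr3 <- GenomicRanges::GRangesList(utr3)
    bad <- !names(utr3) %in% genes$gene_id
    if (any(bad)) stop("3'UTR list contains unknown gene ids")
  } else {
    utr3 <- GenomicRanges::GRangesList()
  }
  structure(list(genes = genes, exons = exons, introns = introns,
                 utr3 = utr3),
            class = "cs_annotation")
}

#' Read gene annotation from GTF
#'
#' Uses `gene`, `exon` and `three_prime_utr` features; introns are derived
#' from the exon structure.
#'
#' @param path GTF file.
#' @return A `cs_annotation` object.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation GTF not found: ", path)
  gtf <- rtracklayer::import(path, format = "gtf")
  genes <- gtf[gtf$type == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  ex <- gtf[gtf$type == "exon"]
  exl <- GenomicRanges::split(GenomicRanges::granges(ex), ex$gene_id)
  u3 <- gtf[gtf$type == "three_prime_utr"]
  u3l <- if (length(u3)) {
    GenomicRanges::split(GenomicRanges::granges(u3), u3$gene_id)
  } else NULL
  gene_annotation(genes, exl, u3l)
}

#' Write a gene annotation to GTF
#' @param annotation `cs_annotation`.
#' @param path output file.
#' @export
write_annotation_gtf <- function(annotation, path) {
  g <- annotation$genes
  lines <- character(0)
  fmt <- function(gr, type, gid) {
    sprintf("%s\tcondensyn\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
            as.character(GenomicRanges::seqnames(gr)), type,
            GenomicRanges::start(gr), GenomicRanges::end(gr),
            as.character(GenomicRanges::strand(gr)), gid)
  }
  for (i in seq_along(g)) {
    gid <- g$gene_id[i]
    lines <- c(lines, fmt(g[i], "gene", gid),
               fmt(annotation$exons[[gid]], "exon", gid))
    if (gid %in% names(annotation$utr3)) {
      lines <- c(lines, fmt(annotation$utr3[[gid]], "three_prime_utr", gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Construct a crosslink track
#'
#' Per-sample sparse map of crosslink sites: one row per (contig, position,
#' strand) with a positive cDNA count. Positions are 1-based nucleotides.
#'
#' @param sites data.frame/data.table with columns `chrom`, `pos`, `strand`,
#'   `count`.
#' @param sample_id sample identifier.
#' @return A `cs_track`: a data.table keyed by (chrom, strand, pos) with
#'   attributes `sample_id` and `library_size`.
#' @export
crosslink_track <- function(sites, sample_id) {
  dt <- as.data.table(sites)[, .(chrom, pos = as.integer(pos),
                                 strand, count = as.integer(count))]
  if (nrow(dt) && any(dt$count < 1L)) stop("cDNA counts must be >= 1")
  dt <- dt[, .(count = sum(count)), by = .(chrom, strand, pos)]
  setkey(dt, chrom, strand, pos)
  setattr(dt, "sample_id", sample_id)
  setattr(dt, "library_size", sum(dt$count))
  setattr(dt, "class", c("cs_track", class(dt)))
  dt
}

#' Read a crosslink BED6 file
#'
#' BED columns: chrom, start (0-based), end = start + 1, name, score
#' (cDNA count, integer >= 1), strand. Malformed lines and records on
#' contigs absent from the genome are fatal.
#'
#' @param path BED6 file.
#' @param genome optional genome; if given, contigs and bounds are checked.
#' @param sample_id sample identifier (defaults to the file stem).
#' @return A `cs_track`.
#' @export
read_crosslink_bed <- function(path, genome = NULL, sample_id = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (is.null(sample_id)) sample_id <- sub("\\.bed$", "", basename(path))
  raw <- readLines(path)
  if (!length(raw)) {
    return(crosslink_track(data.table(chrom = character(), pos = integer(),
                                      strand = character(), count = integer()),
                           sample_id))
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 6)) {
    stop("malformed BED line ", which(nfield < 6)[1], " in ", path)
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2]))
  score <- suppressWarnings(as.numeric(m[, 5]))
  bad <- is.na(start) | is.na(score) | !m[, 6] %in% c("+", "-") |
    score < 1 | score != round(score)
  if (any(bad)) stop("malformed BED line ", which(bad)[1], " in ", path)
  dt <- data.table(chrom = m[, 1], pos = start + 1L, strand = m[, 6],
                   count = as.integer(score))
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    unk <- !dt$chrom %in% names(lens)
    if (any(unk)) {
      stop("BED record on unknown contig '", dt$chrom[unk][1], "' in ", path)
    }
    if (any(dt$pos > lens[dt$chrom])) {
      stop("BED record beyond contig end in ", path)
    }
  }
  crosslink_track(dt, sample_id)
}

#' Write a crosslink track as sorted BED6
#' @param track `cs_track`.
#' @param path output file.
#' @export
write_crosslink_bed <- function(track, path) {
  dt <- as.data.table(track)[order(chrom, pos, strand)]
  out <- dt[, sprintf("%s\t%d\t%d\t.\t%d\t%s",
                      chrom, pos - 1L, pos, count, strand)]
  writeLines(out, path)
  invisible(path)
}

#' Read a sample manifest TSV
#'
#' Required columns: sample_id, experiment, variant, condition, batch,
#' replicate. Sample ids must be unique.
#'
#' @param path TSV file.
#' @return data.table.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- fread(path, sep = "\t", colClasses = list(character = "sample_id"))
  need <- c("sample_id", "experiment", "variant", "condition", "batch",
            "replicate")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         man$sample_id[duplicated(man$sample_id)][1])
  }
  man
}

#' Load all pipeline inputs
#'
#' @param genome_path FASTA.
#' @param annotation_path GTF.
#' @param manifest_path manifest TSV.
#' @param track_paths named character vector of BED paths; names are sample
#'   ids and must each match one manifest row.
#' @return list(genome, annotation, manifest, tracks).
#' @export
load_inputs <- function(genome_path, annotation_path, manifest_path,
                        track_paths) {
  genome <- read_genome(genome_path)
  annotation <- read_annotation(annotation_path)
  manifest <- read_manifest(manifest_path)
  if (is.null(names(track_paths))) {
    names(track_paths) <- sub("\\.bed$", "", basename(track_paths))
  }
  unknown <- setdiff(names(track_paths), manifest$sample_id)
  if (length(unknown)) stop("track sample not in manifest: ", unknown[1])
  tracks <- lapply(names(track_paths), function(sid) {
    read_crosslink_bed(track_paths[[sid]], genome = genome, sample_id = sid)
  })
  names(tracks) <- names(track_paths)
  list(genome = genome, annotation = annotation, manifest = manifest,
       tracks = tracks)
}

#' Derive the regions used for crosslink thresholding
#'
#' Each intron and each intergenic stretch is its own region; the exons of
#' each gene are merged into a single (possibly multi-interval) region.
#' Intergenic regions are the strand-agnostic complement of the union of
#' gene spans, split at gene boundaries.
#'
#' @param annotation `cs_annotation`.
#' @param genome genome (for contig lengths).
#' @return `GRanges` with columns `kind` (intron/merged_exons/intergenic),
#'   `gene_id`, `region_id`. Merged-exon regions share one `region_id`
#'   across their intervals.
#' @export
derive_threshold_regions <- function(annotation, genome) {
  lens <- genome_lengths(genome)
  out <- list()
  for (gid in annotation$genes$gene_id) {
    ex <- GenomicRanges::reduce(annotation$exons[[gid]])
    ex$kind <- "merged_exons"
    ex$gene_id <- gid
    ex$region_id <- paste0(gid, ":exons")
    out[[length(out) + 1L]] <- ex
    intr <- annotation$introns[[gid]]
    if (length(intr)) {
      intr$kind <- "intron"
      intr$gene_id <- gid
      intr$region_id <- paste0(gid, ":intron", seq_along(intr))
      out[[length(out) + 1L]] <- intr
    }
  }
  spans <- GenomicRanges::granges(annotation$genes)
  GenomicRanges::strand(spans) <- "*"
  si <- GenomeInfoDb::Seqinfo(seqnames = names(lens), seqlengths = unname(lens))
  GenomeInfoDb::seqlevels(spans) <- names(lens)
  GenomeInfoDb::seqinfo(spans) <- si
  ig <- GenomicRanges::gaps(GenomicRanges::reduce(spans))
  ig <- ig[GenomicRanges::strand(ig) == "*"]
  if (length(ig)) {
    ig$kind <- "intergenic"
    ig$gene_id <- NA_character_
    ig$region_id <- paste0("intergenic", seq_along(ig))
    out[[length(out) + 1L]] <- ig
  }
  res <- suppressWarnings(do.call(c, out))
  GenomeInfoDb::seqlevels(res) <- names(lens)
  GenomeInfoDb::seqinfo(res) <- si
  res
}

#' Extract sequence windows oriented in transcript direction
#'
#' Offset 0 is the anchor nucleotide itself; negative offsets are 5' of it
#' in transcript orientation. Minus-strand windows are reverse-complemented.
#' Parts of the window beyond the contig are padded with N and flagged.
#'
#' @param genome genome.
#' @param chrom,pos,strand vectors describing anchor sites (1-based pos).
#' @param span `c(left, right)` window in transcript coordinates, e.g.
#'   `c(-40, 40)`.
#' @return character vector of windows of width `right - left + 1`, with
#'   attribute `truncated` (logical vector).
#' @export
extract_oriented_window <- function(genome, chrom, pos, strand, span) {
  seqs <- genome_as_character(genome)
  lens <- nchar(seqs)
  left <- span[1]; right <- span[2]
  w <- right - left + 1L
  plus <- strand == "+"
  gstart <- ifelse(plus, pos + left, pos - right)
  gend <- ifelse(plus, pos + right, pos - left)
  cl <- lens[chrom]
  s <- pmax(gstart, 1L)
  e <- pmin(gend, cl)
  truncated <- gstart < 1L | gend > cl
  core <- substring(seqs[chrom], s, e)
  padl <- pmax(0L, 1L - gstart)
  padr <- pmax(0L, gend - cl)
  out <- paste0(strrep("N", padl), core, strrep("N", padr))
  if (any(!plus)) {
    out[!plus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(out[!plus])))
  }
  stopifnot(all(nchar(out) == w))
  attr(out, "truncated") <- unname(truncated)
  out
}

#' Centered rolling mean
#'
#' Output has length `length(x) - window + 1`; element i is the mean of
#' `x[i:(i + window - 1)]` (i.e. the window aligned so that the output is
#' the valid part of a centred moving average).
#'
#' @param x numeric vector.
#' @param window window size (>= 1, <= length(x)).
#' @export
rolling_mean <- function(x, window) {
  if (window < 1) stop("window must be >= 1")
  if (window > length(x)) stop("window larger than input")
  if (window == 1) return(as.numeric(x))
  cs <- cumsum(c(0, x))
  n <- length(x) - window + 1L
  (cs[(window + 1):(length(x) + 1)] - cs[1:n]) / window
}

#' Library-size normalized, smoothed crosslink coverage over an interval
#'
#' Counts are divided by the track library size, expanded to a
#' per-nucleotide vector over the interval, and smoothed with a rolling
#' mean (window 20 nt by default), the convention used for comparative
#' visualization of iCLIP tracks.
#'
#' @param track `cs_track`.
#' @param contig,start,end,site_strand interval (1-based, closed).
#' @param window rolling-mean window.
#' @return data.table(pos, value) of smoothed normalized coverage.
#' @export
smoothed_track <- function(track, contig, start, end, site_strand,
                           window = 20) {
  libsz <- attr(track, "library_size")
  dt <- as.data.table(track)
  sel <- dt[chrom == contig & strand == site_strand &
              pos >= start & pos <= end]
  v <- numeric(end - start + 1L)
  if (nrow(sel)) v[sel$pos - start + 1L] <- sel$count / libsz
  sm <- rolling_mean(v, min(window, length(v)))
  offset <- (min(window, length(v)) - 1L) %/% 2L
  data.table(pos = start + offset + seq_along(sm) - 1L, value = sm)
}

#' Write a per-position value track as bedGraph
#'
#' Runs of equal values are collapsed into intervals; positions are
#' converted to the 0-based half-open BED convention on output.
#'
#' @param values data.table(pos, value) on one contig (e.g. from
#'   [smoothed_track()]).
#' @param contig contig name.
#' @param path output file.
#' @export
write_bedgraph <- function(values, contig, path) {
  dt <- as.data.table(values)[order(pos)]
  if (!nrow(dt)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  run <- cumsum(c(TRUE, diff(dt$pos) != 1L | diff(dt$value) != 0))
  agg <- dt[, .(start = min(pos) - 1L, end = max(pos), value = value[1]),
            by = .(run = run)]
  writeLines(sprintf("%s\t%d\t%d\t%g", contig, agg$start, agg$end,
                     agg$value), path)
  invisible(path)
}
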