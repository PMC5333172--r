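#' Write / read locus sequences as FASTA
#'
#' @param x a `regevo_genotype` or a named character vector of sequences
#' @param path file path
#' @return `read_fasta_loci` returns a named character vector
#' @export
write_fasta_loci <- function(x, path) {
  seqs <- if (inherits(x, "regevo_genotype")) genotype_sequences(x) else x
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname write_fasta_loci
#' @export
read_fasta_loci <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write a site annotation as BED6
#'
#' 0-based half-open coordinates; chrom = locus, name = TF,
#' score = round(E * 100), strand as given.
#'
#' @param sites data.frame(tf, locus, start, length, strand, E)
#' @param path file path
#' @return invisibly, the path
#' @export
write_bed_sites <- function(sites, path) {
  df <- data.frame(chrom = sites$locus,
                   start = sites$start,
                   end = sites$start + sites$length,
                   name = sites$tf,
                   score = as.integer(round(sites$E * 100)),
                   strand = sites$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED6 site file
#'
#' Lines are validated first (a malformed line is reported with its line
#' number), then parsed with rtracklayer.
#'
#' @param path file path
#' @return data.frame(tf, locus, start, length, strand, E)
#' @export
read_bed_sites <- function(path) {
  lines <- readLines(path)
  nf <- vapply(strsplit(lines, "\t", fixed = TRUE), length, 0L)
  bad <- which(nzchar(lines) & nf < 6)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": expected >= 6 fields, found ",
         nf[bad[1]])
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(tf = gr$name,
             locus = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             length = GenomicRanges::width(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             E = gr$score / 100,
             stringsAsFactors = FALSE)
}

#' Write / read interval sets (masks, CRMs, footprints) as BED3+name
#'
#' @param intervals named list of data.frame(start, end), one per locus
#' @param path file path
#' @param name feature name written in column 4
#' @return `read_bed_intervals` returns the named list form
#' @export
write_bed_intervals <- function(intervals, path, name = "region") {
  rows <- do.call(rbind, lapply(names(intervals), function(g) {
    iv <- intervals[[g]]
    if (nrow(iv) == 0) return(NULL)
    data.frame(chrom = g, start = iv$start, end = iv$end, name = name)
  }))
  if (is.null(rows))
    rows <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), name = character(0))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_intervals
#' @export
read_bed_intervals <- function(path) {
  if (file.size(path) == 0) return(list())
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  out <- split(data.frame(start = df$V2, end = df$V3), df$V1)
  lapply(out, function(d) { rownames(d) <- NULL; d })
}

#' Run manifest
#'
#' Records the configuration snapshot, global seed, derived stage seeds,
#' package version and MD5 checksums of every written output: enough to
#' reproduce and verify a run bit-for-bit.
#'
#' @param out_dir pipeline output directory
#' @param config configuration list
#' @param seed global seed
#' @param stage_seeds named integer vector
#' @param status "ok" or "failed:<stage>"
#' @return the manifest list, invisibly written to
#'   `out_dir/manifest.json`
#' @export
write_manifest <- function(out_dir, config, seed, stage_seeds,
                           status = "ok") {
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(package = "regevo",
                   version = as.character(packageVersion("regevo")),
                   seed = seed, stage_seeds = as.list(stage_seeds),
                   status = status, config = config,
                   checksums = as.list(setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
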