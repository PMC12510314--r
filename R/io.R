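# Plain-text readers/writers: the generators emit the same formats the
# analysis functions read.

#' Read / write binding-plate tables
#'
#' CSV with columns `well`, `ligand_conc_uM`, `fnorm`, `replicate`, and
#' optionally `treatment`, `aging`, `incubation_h`, `init_fluor`,
#' `well_flag`.
#'
#' @param series binding-series data frame.
#' @param path file path.
#' @return `read_binding_plate` returns the data frame;
#'   `write_binding_plate` returns `path` invisibly.
#' @export
write_binding_plate <- function(series, path) {
  write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binding_plate
#' @export
read_binding_plate <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write paired RNA/RNC count tables
#'
#' Tab-separated genes x samples matrix with a two-row header above the
#' sample columns: row 1 the assay (`RNA`/`RNC`), row 2 the group; the
#' first column holds gene ids. Replicate numbers are assigned by column
#' order within each (assay, group) cell.
#'
#' @param gp a [gene_pair_counts()].
#' @param path file path.
#' @return `read_pair_counts` returns a [gene_pair_counts()];
#'   `write_pair_counts` returns `path` invisibly.
#' @export
write_pair_counts <- function(gp, path) {
  stopifnot(inherits(gp, "gene_pair_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#assay", gp$sample_meta$assay), collapse = "\t"), con)
  writeLines(paste(c("#group", gp$sample_meta$group), collapse = "\t"), con)
  write.table(data.frame(gene_id = rownames(gp$counts), gp$counts,
                         check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_counts
#' @export
read_pair_counts <- function(path) {
  hdr <- readLines(path, n = 2L)
  assay <- strsplit(hdr[1], "\t")[[1]][-1]
  group <- strsplit(hdr[2], "\t")[[1]][-1]
  tab <- read.delim(path, skip = 2L, header = FALSE,
                    stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  replicate <- stats::ave(seq_along(assay),
                          paste(assay, group), FUN = seq_along)
  meta <- data.frame(
    sample = paste(assay, group, replicate, sep = "_"),
    assay = assay, group = group, replicate = replicate)
  colnames(counts) <- meta$sample
  gene_pair_counts(counts, meta)
}

#' Write a haplotype matrix as a minimal haploid VCF (plus popmap)
#'
#' Sites are written as biallelic A/T records with haploid `GT` calls
#' (`0`, `1`, or `.` for missing). The population map is a two-column
#' headerless TSV (sample, label).
#'
#' @param hm a [haplotype_matrix()].
#' @param vcf_path,popmap_path output paths.
#' @return `vcf_path`, invisibly.
#' @export
write_haplotype_vcf <- function(hm, vcf_path, popmap_path = NULL) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  samples <- sprintf("hap%03d", seq_len(nrow(hm$alleles)))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", hm$contig),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt <- t(hm$alleles)
  gt[is.na(gt)] <- "."
  body <- vapply(seq_len(ncol(hm$alleles)), function(s) {
    paste(c(hm$contig, format(hm$positions[s], scientific = FALSE),
            ".", "A", "T", ".", "PASS", ".", "GT", gt[s, ]),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), vcf_path)
  if (!is.null(popmap_path)) {
    writeLines(paste(samples, hm$pop_labels, sep = "\t"), popmap_path)
  }
  invisible(vcf_path)
}

#' Read a VCF plus population map into a haplotype matrix
#'
#' Haploid `GT` calls are used as-is; diploid calls (phased or not) are
#' split into two haplotypes per sample (suffixes `_a`/`_b`).
#'
#' @param vcf_path VCF file (uncompressed or bgzipped; parsed by vcfR).
#' @param popmap two-column data frame (sample, label) or path to a
#'   headerless TSV.
#' @param region_start,region_end optional region bounds (defaults: 1 and
#'   the last position).
#' @return a [haplotype_matrix()].
#' @export
read_haplotype_vcf <- function(vcf_path, popmap, region_start = 1L,
                               region_end = NULL) {
  if (is.character(popmap)) {
    popmap <- read.delim(popmap, header = FALSE,
                         col.names = c("sample", "label"))
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  pos <- as.numeric(v@fix[, "POS"])
  contig <- v@fix[1, "CHROM"]
  diploid <- any(grepl("[/|]", gt), na.rm = TRUE)
  if (diploid) {
    a1 <- sub("[/|].*", "", gt)
    a2 <- sub(".*[/|]", "", gt)
    alle <- rbind(t(a1), t(a2))
    samp <- c(paste0(colnames(gt), "_a"), paste0(colnames(gt), "_b"))
    labels <- popmap$label[match(rep(colnames(gt), 2L), popmap$sample)]
  } else {
    alle <- t(gt)
    samp <- colnames(gt)
    labels <- popmap$label[match(samp, popmap$sample)]
  }
  if (anyNA(labels)) stop("popmap is missing samples present in the VCF",
                          call. = FALSE)
  alle[alle == "."] <- NA
  storage.mode(alle) <- "numeric"
  ord <- order(pos)
  haplotype_matrix(alle[, ord, drop = FALSE], pos[ord], labels,
                   contig = contig, region_start = region_start,
                   region_end = region_end)
}

#' Write a window scan as BED-like TSV
#'
#' @param scan a [window_scan()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  write.table(scan, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write FASTA as named uppercase strings
#'
#' @param path FASTA file.
#' @param seqs named character vector of sequences.
#' @return `read_fasta_strings` returns a named character vector.
#' @export
read_fasta_strings <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(toupper(vapply(x, as.character, character(1))), names(x))
}

#' @rdname read_fasta_strings
#' @export
write_fasta_strings <- function(seqs, path) {
  seqinr::write.fasta(as.list(unname(seqs)), names(seqs), path)
  invisible(path)
}

#' Read a bisulfite locus from FASTA (first record = reference)
#'
#' @param path FASTA with the unconverted reference first, clones after.
#' @param strand amplicon strand, passed to [bisulfite_locus()].
#' @return a [bisulfite_locus()].
#' @export
read_bisulfite_fasta <- function(path, strand = "top") {
  seqs <- read_fasta_strings(path)
  if (length(seqs) < 2L) stop("need a reference plus >= 1 clone", call. = FALSE)
  bisulfite_locus(seqs[[1]], seqs[-1], region_id = names(seqs)[1],
                  strand = strand)
}

#' Read / write germination trial CSV
#'
#' Columns `genotype`, `treatment`, `replicate`, `time_h`,
#' `n_germinated`, `n_total`.
#'
#' @param trials germination data frame.
#' @param path file path.
#' @return `read_germination_csv` returns the data frame.
#' @export
write_germination_csv <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_germination_csv
#' @export
read_germination_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
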