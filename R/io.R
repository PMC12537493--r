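# Readers and writers for the standard formats the pipeline touches.
# Internal coordinates are 0-based half-open everywhere; conversion happens
# only at these I/O boundaries (allc and GFF3 are 1-based, BED is 0-based).

#' Read an allc-style site table
#'
#' TSV with columns chrom, pos (1-based), strand, context, mc_count,
#' total_count (a header is optional; extra columns are ignored).
#' Positions are converted to the internal 0-based convention.
#'
#' @param path file path (gzip-transparent)
#' @return data.table: chrom, pos (0-based), strand, context, reads_meth,
#'   reads_total
#' @export
read_allc <- function(path) {
  cols <- c("chrom", "pos", "strand", "context", "mc_count", "total_count")
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    warning("empty allc file: ", path)
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character(),
                                  context = character(),
                                  reads_meth = integer(),
                                  reads_total = integer()))
  }
  has_header <- grepl("chrom", first, fixed = TRUE)
  dt <- data.table::fread(path, header = has_header)
  if (!has_header) data.table::setnames(dt, seq_along(cols), cols)
  bad <- which(dt$mc_count > dt$total_count | dt$mc_count < 0 |
                 dt$total_count < 0)
  if (length(bad))
    stop("mc_count > total_count at line(s) ",
         paste(head(bad + has_header, 5), collapse = ", "), " of ", path,
         call. = FALSE)
  if (!all(dt$context %in% c("CG", "CHG", "CHH")))
    stop("unknown context values in ", path, call. = FALSE)
  data.table::data.table(chrom = dt$chrom, pos = as.integer(dt$pos) - 1L,
                         strand = dt$strand, context = dt$context,
                         reads_meth = as.integer(dt$mc_count),
                         reads_total = as.integer(dt$total_count))
}

#' Write an allc-style site table (inverse of [read_allc()])
#'
#' @param sites data.table with internal 0-based `pos`
#' @param path output path
#' @export
write_allc <- function(sites, path) {
  out <- data.table::data.table(
    chrom = sites$chrom, pos = sites$pos + 1L, strand = sites$strand,
    context = sites$context, mc_count = sites$reads_meth,
    total_count = sites$reads_total)
  data.table::fwrite(out, path, sep = "\t")
}

#' Read gene annotation from GFF3 or BED
#'
#' GFF3 (1-based closed) and BED (0-based half-open) are unified to the
#' internal 0-based half-open convention; the TSS is the strand-aware 5'
#' end.
#'
#' @param path annotation file; dialect chosen by extension (`.gff`,
#'   `.gff3`, `.bed`)
#' @param feature GFF3 feature type to keep
#' @return data.table: gene_id, chrom, start, end (half-open), strand, tss
#' @export
read_annotation <- function(path, feature = "gene") {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == feature]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID)
           else as.character(gr$Name)
    dt <- data.table::data.table(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # 1-based closed -> half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)))
  } else if (ext == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    dt <- data.table::data.table(
      gene_id = gr$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)))
  } else stop("unknown annotation dialect: ", ext, call. = FALSE)
  dup <- unique(dt$gene_id[duplicated(dt$gene_id)])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(head(dup, 5), collapse = ", "),
         call. = FALSE)
  dt[, tss := ifelse(strand == "-", end - 1L, start)]
  dt[]
}

#' Read a genotype matrix from a minimal VCF or a TSV matrix
#'
#' Biallelic VCF records are coded from GT (haploid mode: 0/1 with
#' heterozygotes set to NA; diploid mode: 0/1/2 alternate-allele dosage).
#' Multiallelic records are skipped (counted). A TSV is read as an
#' accessions x SNPs integer matrix with a header row of SNP ids and first
#' column of accession ids.
#'
#' @param path input file
#' @param ploidy 1 (default, inbred accessions) or 2
#' @return list: `genotypes` (accessions x SNPs), `positions` (data.table
#'   chrom/pos for VCF input, else NULL), `skipped_multiallelic`
#' @export
read_genotypes <- function(path, ploidy = 1L) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", vcfR::getALT(v))
    gt <- vcfR::extract.gt(v, element = "GT")[!multi, , drop = FALSE]
    fix <- v@fix[!multi, , drop = FALSE]
    dose <- function(g) {
      alleles <- strsplit(gsub("\\|", "/", g), "/")
      vapply(alleles, function(a) {
        a <- suppressWarnings(as.integer(a))
        if (anyNA(a)) return(NA_integer_)
        sum(a)
      }, 0L)
    }
    D <- apply(gt, 2, dose)
    if (is.null(dim(D))) D <- matrix(D, nrow = nrow(gt),
                                     dimnames = list(NULL, colnames(gt)))
    if (ploidy == 1L) {
      H <- D
      H[D == 1L] <- NA_integer_   # heterozygote in haploid mode
      H[D == 2L] <- 1L
      D <- H
    }
    G <- t(D)
    colnames(G) <- fix[, "ID"]
    list(genotypes = G,
         positions = data.table::data.table(
           snp = fix[, "ID"], chrom = fix[, "CHROM"],
           pos = as.integer(fix[, "POS"]) - 1L),
         skipped_multiallelic = sum(multi))
  } else {
    dt <- data.table::fread(path)
    G <- as.matrix(dt[, -1, drop = FALSE])
    rownames(G) <- as.character(dt[[1]])
    storage.mode(G) <- "integer"
    list(genotypes = G, positions = NULL, skipped_multiallelic = 0L)
  }
}

#' Write a genotype matrix as TSV (inverse of the TSV branch of
#' [read_genotypes()])
#'
#' @param genotypes accessions x SNPs matrix
#' @param path output path
#' @export
write_genotypes <- function(genotypes, path) {
  dt <- data.table::data.table(accession = rownames(genotypes))
  dt <- cbind(dt, data.table::as.data.table(genotypes))
  data.table::fwrite(dt, path, sep = "\t")
}

#' Read/write a genes x accessions numeric matrix TSV
#'
#' Header row of accession ids, first column of gene ids.
#'
#' @param path file path
#' @return numeric matrix with dimnames
#' @export
read_matrix_tsv <- function(path) {
  dt <- data.table::fread(path)
  M <- as.matrix(dt[, -1, drop = FALSE])
  rownames(M) <- as.character(dt[[1]])
  M
}

#' @rdname read_matrix_tsv
#' @param m matrix to write
#' @param id_col name of the first (id) column
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  dt <- data.table::data.table(id = rownames(m))
  data.table::setnames(dt, "id", id_col)
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::fwrite(dt, path, sep = "\t")
}

#' Write a reproducibility manifest for a pipeline run
#'
#' @param path output JSON path
#' @param config named list of thresholds and inputs
#' @param seed master seed
#' @export
write_manifest <- function(path, config, seed) {
  manifest <- list(config = config, seed = seed,
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("epiqtl")),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
}
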