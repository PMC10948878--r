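#' Read and write tab-separated tables
#'
#' Thin wrappers standardizing the TSV dialect used across the pipeline
#' (header, tab separator, no quoting, no row names).
#'
#' @param path file path.
#' @param x data.frame to write.
#' @return `read_tsv_table()` returns a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-caller somatic calls as a VCF
#'
#' Emits a minimal VCF v4.2 with the caller name and the read-count,
#' database and annotation fields carried in INFO (keys CALLER, VCLASS,
#' TDP, TAD, NDP, NAD, DBSNP, COSMIC, GENE, CSQ), the dialect read back by
#' [read_caller_vcf()].
#'
#' @param calls per-caller call data.frame (one caller, one sample).
#' @param path output path.
#' @export
write_caller_vcf <- function(calls, path) {
  if (length(unique(calls$caller)) > 1) stop("one VCF per caller")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=primet",
    sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
      c("CALLER", "VCLASS", "TDP", "TAD", "NDP", "NAD", "DBSNP", "COSMIC", "GENE", "CSQ"),
      c("String", "String", "Integer", "Integer", "Integer", "Integer",
        "Integer", "Integer", "String", "String"),
      c("caller name", "SNV or indel", "tumor depth", "tumor alt reads",
        "normal depth", "normal alt reads", "in dbSNP", "in COSMIC",
        "gene symbol", "consequence")
    ),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", sep = "\t")
  )
  info <- sprintf(
    "CALLER=%s;VCLASS=%s;TDP=%d;TAD=%d;NDP=%d;NAD=%d;DBSNP=%d;COSMIC=%d;GENE=%s;CSQ=%s",
    calls$caller, calls$variant_class, calls$tumor_depth, calls$tumor_alt_reads,
    calls$normal_depth, calls$normal_alt_reads, as.integer(calls$in_dbsnp),
    as.integer(calls$in_cosmic), calls$gene, calls$consequence
  )
  body <- paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", ".",
    info,
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a per-caller VCF back into the call-table dialect
#'
#' @param path VCF written by [write_caller_vcf()] (or any VCF carrying
#'   the same INFO keys).
#' @param sample_id sample name to stamp on the rows.
#' @param caller caller name; defaults to the INFO CALLER field.
#' @return per-caller call data.frame as consumed by [merge_callers()].
#' @export
read_caller_vcf <- function(path, sample_id, caller = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info_num <- function(key) {
    as.integer(vcfR::extract.info(v, element = key))
  }
  info_chr <- function(key) as.character(vcfR::extract.info(v, element = key))
  caller_col <- info_chr("CALLER")
  if (is.null(caller)) caller <- caller_col
  data.frame(
    sample_id = sample_id,
    caller = caller,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    variant_class = info_chr("VCLASS"),
    tumor_depth = info_num("TDP"),
    tumor_alt_reads = info_num("TAD"),
    normal_depth = info_num("NDP"),
    normal_alt_reads = info_num("NAD"),
    in_dbsnp = info_num("DBSNP") == 1,
    in_cosmic = info_num("COSMIC") == 1,
    gene = info_chr("GENE"),
    consequence = info_chr("CSQ")
  )
}

#' Read gene transcription intervals from BED or GFF3
#'
#' BED input is used natively (0-based half-open, gene symbol in column
#' 4); GFF3 is converted on read (gene rows, symbol from `Name`, `gene`
#' or `ID`). Requires the rtracklayer package for GFF3.
#'
#' @param path interval file; format chosen by extension (.bed vs
#'   .gff/.gff3).
#' @return data.frame `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
read_gene_intervals <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- utils::read.delim(path,
      header = FALSE, stringsAsFactors = FALSE,
      comment.char = "#"
    )
    return(data.frame(
      gene = bed[[4]], chrom = as.character(bed[[1]]),
      start = bed[[2]], end = bed[[3]]
    ))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  md <- as.data.frame(gr)
  name <- if ("Name" %in% names(md)) {
    md$Name
  } else if ("gene" %in% names(md)) md$gene else md$ID
  data.frame(
    gene = as.character(name), chrom = as.character(md$seqnames),
    start = md$start - 1L, end = md$end
  )
}

#' Read a one-symbol-per-line gene list
#'
#' @param path text file, one gene symbol per line; blank lines and
#'   `#` comments ignored.
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a genes x samples expression matrix from TSV
#'
#' First column holds gene identifiers; remaining columns are samples.
#'
#' @param path TSV file.
#' @return numeric matrix with gene row names.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param x matrix to write.
#' @param id_col name for the gene-id column (default "gene").
#' @export
write_expression_tsv <- function(x, path, id_col = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE)
  names(df)[1] <- id_col
  write_tsv_table(df, path)
}

#' Read a metacluster rule table from a YAML config
#'
#' The file holds a list of rules, each with `label`, optional
#' `markers_high` / `markers_low` lists and an optional `threshold`
#' (default 0.5); rule order is match order.
#'
#' @param path YAML file.
#' @return rule data.frame as used by [assign_metaclusters()].
#' @export
read_metacluster_rules <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(rbind, lapply(y, function(r) {
    data.frame(
      label = r$label,
      markers_high = paste(unlist(r$markers_high), collapse = ";"),
      markers_low = paste(unlist(r$markers_low), collapse = ";"),
      threshold = if (is.null(r$threshold)) 0.5 else r$threshold
    )
  }))
}
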