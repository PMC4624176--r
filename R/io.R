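## Readers check structure and report the offending line, writers emit
## plain headered TSV so every artifact is diffable and round-trips.

read_tsv_checked <- function(path, required, what = "table") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop("malformed ", what, " in ", path, ": line ", bad[1] + 0L,
         " has ", nf[bad[1]], " fields, expected ", nf[1])
  x <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  ## identifier-like columns stay character even when they look numeric
  id_cols <- intersect(c("chrom", "gene", "gene_a", "gene_b", "line", "id",
                         "sex", "pool", "exposure", "replicate", "date"),
                       names(x))
  for (cc in id_cols) x[[cc]] <- as.character(x[[cc]])
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(what, " ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  x
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write elution tables
#'
#' Headered TSV with one row per fly.
#'
#' @param path file path.
#' @param x elution `data.frame`.
#' @return the table / the path, invisibly.
#' @export
read_elutions <- function(path) {
  x <- read_tsv_checked(path, c("sex", "exposure", "replicate", "minute"),
                        "elution table")
  if (any(x$minute <= 0)) stop("elution minutes must be positive")
  bad <- setdiff(unique(x$exposure), c("E1", "E2"))
  if (length(bad)) stop("unknown exposure label(s): ",
                        paste(bad, collapse = ", "))
  x
}

#' @rdname read_elutions
#' @export
write_elutions <- function(x, path) write_tsv(x, path)

#' Read / write pool-count tables
#'
#' Headered TSV with columns `chrom`, `pos`, `alt_S`, `d_S`, `alt_R`,
#' `d_R` (extra columns preserved).
#'
#' @param path file path.
#' @param x pool-counts `data.frame`.
#' @return the table / the path, invisibly.
#' @export
read_pool_counts <- function(path) {
  x <- read_tsv_checked(path, c("chrom", "pos", "alt_S", "d_S", "alt_R", "d_R"),
                        "pool counts")
  if (any(x$alt_S > x$d_S | x$alt_R > x$d_R | x$alt_S < 0 | x$alt_R < 0))
    stop("allele counts must lie in [0, depth]")
  x
}

#' @rdname read_pool_counts
#' @export
write_pool_counts <- function(x, path) write_tsv(x, path)

#' Write a founder panel as a minimal VCF
#'
#' Emits a VCFv4.2 file with one sample per founder line and homozygous
#' GT calls (`0/0` or `1/1`) — the minimal representation of a fully
#' inbred biallelic panel.
#'
#' @param panel a `founder_panel`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$line_ids), collapse = "\t")),
             con)
  gt <- ifelse(panel$geno == 1L, "1/1", "0/0")
  body <- cbind(panel$sites$chrom, panel$sites$pos, ".",
                panel$sites$ref, panel$sites$alt, ".", ".", ".", "GT", gt)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a founder panel from a minimal VCF
#'
#' Accepts homozygous biallelic GT records (`0/0`, `1/1`, `0|0`,
#' `1|1`); anything else is rejected, since the panel model assumes
#' fully inbred lines.
#'
#' @param path VCF path.
#' @param map genetic map to attach (see [default_genetic_map()]).
#' @return a `founder_panel`.
#' @export
read_panel_vcf <- function(path, map = default_genetic_map()) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ok_hom <- gt %in% c("0/0", "1/1", "0|0", "1|1")
  if (!all(ok_hom))
    stop("non-homozygous or missing genotype(s); founder panels must be ",
         "fully inbred (first offender: ", gt[which(!ok_hom)[1]], ")")
  geno <- matrix(as.integer(gt %in% c("1/1", "1|1")), nrow(gt), ncol(gt),
                 dimnames = list(NULL, colnames(gt)))
  fix <- vcfR::getFIX(v)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  structure(list(line_ids = colnames(gt), sites = sites, geno = geno,
                 map = map), class = "founder_panel")
}

#' Read / write a founder panel as a TSV genotype matrix
#'
#' Site rows, line columns: `chrom`, `pos`, `ref`, `alt`, then one 0/1
#' column per line.
#'
#' @param panel a `founder_panel`.
#' @param path file path.
#' @param map genetic map to attach on read.
#' @return the path / a `founder_panel`.
#' @export
write_panel_tsv <- function(panel, path) {
  write_tsv(cbind(panel$sites, as.data.frame(panel$geno)), path)
}

#' @rdname write_panel_tsv
#' @export
read_panel_tsv <- function(path, map = default_genetic_map()) {
  x <- read_tsv_checked(path, c("chrom", "pos", "ref", "alt"), "panel matrix")
  line_ids <- setdiff(names(x), c("chrom", "pos", "ref", "alt"))
  if (length(line_ids) < 2) stop("panel matrix needs >= 2 line columns")
  geno <- as.matrix(x[line_ids])
  if (!all(geno %in% c(0L, 1L))) stop("panel genotypes must be 0/1")
  storage.mode(geno) <- "integer"
  structure(list(line_ids = line_ids,
                 sites = x[c("chrom", "pos", "ref", "alt")],
                 geno = geno, map = map),
            class = "founder_panel")
}

#' Read a gene catalog from BED or GFF3
#'
#' Uses `rtracklayer::import`, so coordinate conventions are handled at
#' the boundary exactly once: BED's 0-based half-open intervals and
#' GFF3's 1-based inclusive intervals both arrive as 1-based inclusive
#' ranges internally.  For GFF3, only `type == "gene"` records are kept
#' when present; gene names come from the `Name`/`ID` attribute (GFF3)
#' or the name field (BED).
#'
#' @param path file path ending in `.bed`, `.gff`, `.gff3`.
#' @param format override the extension-based format guess.
#' @return `data.frame` with `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @export
read_gene_catalog <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  md <- as.data.frame(S4Vectors::mcols(gr))
  if (format == "gff3" && "type" %in% names(md) && any(md$type == "gene")) {
    keep <- md$type == "gene"
    gr <- gr[keep]; md <- md[keep, , drop = FALSE]
  }
  gene <- if ("name" %in% names(md)) md$name
          else if ("Name" %in% names(md)) md$Name
          else if ("ID" %in% names(md)) md$ID
          else paste0("gene", seq_along(gr))
  out <- data.frame(gene = as.character(gene),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) stop("duplicate gene ids in ", path)
  rownames(out) <- NULL
  out
}

#' Read / write interaction edge lists
#'
#' Three-column TSV: `gene_a`, `gene_b`, `type` (genetic/physical).
#'
#' @param path file path.
#' @param edges edge-list `data.frame`.
#' @return the table / the path.
#' @export
read_edge_list <- function(path) {
  x <- read_tsv_checked(path, c("gene_a", "gene_b", "type"), "edge list")
  bad <- setdiff(unique(x$type), c("genetic", "physical"))
  if (length(bad)) stop("unknown interaction type(s): ",
                        paste(bad, collapse = ", "))
  x
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(edges, path) write_tsv(edges, path)

#' Export a subnetwork as GraphML
#'
#' @param sub an `igraph` graph (e.g. from [extract_subnetwork()]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_graphml <- function(sub, path) {
  igraph::write_graph(sub, path, format = "graphml")
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns `gene`, `sex`, `pool`, `bio_rep`,
#'   `tech_rep`, `ct`.
#' @return the checked `data.frame`.
#' @export
read_ct_table <- function(path) {
  x <- read_tsv_checked(path, c("gene", "sex", "pool", "bio_rep",
                                "tech_rep", "ct"), "Ct table")
  if (any(x$ct <= 0)) stop("Ct values must be positive")
  bad <- setdiff(unique(x$pool), c("sensitive", "resistant"))
  if (length(bad)) stop("unknown pool label(s): ", paste(bad, collapse = ", "))
  x
}
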