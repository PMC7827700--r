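#' Gene-model annotation from GTF
#'
#' Reads one or more GTF files (GENCODE dialect) into a gene-model
#' annotation: one record per `gene` feature with its exon structure, a
#' biotype collapsed to `coding` / `lncRNA` / `other`, and per-chromosome
#' interval indexes over exon unions and gene spans for fast overlap
#' queries. Coordinates are 1-based inclusive throughout, as in the GTF.
#'
#' Biotype is taken from the `gene_type` attribute (falling back to
#' `gene_biotype`): `protein_coding` maps to `coding`; `lncRNA` and the
#' legacy values `antisense` and `lincRNA` map to `lncRNA`; everything else
#' to `other`. The mature length of a gene is the size of the union of its
#' exon intervals, i.e. what strand-specific exon counting can see.
#'
#' @param paths Character vector of GTF file paths. Coding and lncRNA
#'   annotations may live in separate files; they are merged. Duplicate
#'   `gene_id`s across or within files are an error.
#' @param biotype_filter Optional character vector; keep only genes whose
#'   collapsed biotype is in this set (e.g. `c("coding", "lncRNA")`).
#' @return An object of class `sclnc_annotation`: a list with
#'   * `genes` — tibble with one row per gene: `gene_id`, `gene_name`,
#'     `chrom`, `strand`, `start`, `end`, `biotype`, `n_exons`,
#'     `mature_length`;
#'   * `exons` — `GRanges` of exon-union intervals, one or more per gene,
#'     with a `gene_id` metadata column;
#'   * `spans` — `GRanges` of gene spans named by `gene_id`.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste0(
#'   "chr1\tx\tgene\t101\t200\t.\t+\t.\t",
#'   'gene_id "G1"; gene_type "lncRNA"; gene_name "G1";\n',
#'   "chr1\tx\texon\t101\t200\t.\t+\t.\t",
#'   'gene_id "G1"; gene_type "lncRNA"; gene_name "G1";'
#' ), gtf)
#' ann <- read_gene_models(gtf)
#' ann$genes$mature_length  # 100
#' @export
read_gene_models <- function(paths, biotype_filter = NULL) {
  stopifnot(is.character(paths), length(paths) >= 1)
  for (p in paths) {
    if (!file.exists(p)) stop("GTF file not found: ", p, call. = FALSE)
    validate_gtf_lines(p)
  }
  grl <- lapply(paths, function(p) rtracklayer::import(p, format = "gtf"))
  gr <- suppressWarnings(do.call(c, grl))
  build_annotation_from_gr(gr, biotype_filter = biotype_filter)
}

# Cheap structural validation so parse errors carry a line number.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9) {
      stop(sprintf("malformed GTF line %d in %s: expected 9 tab-separated fields, got %d",
                   i, path, length(f)), call. = FALSE)
    }
    if (is.na(suppressWarnings(as.integer(f[4]))) ||
        is.na(suppressWarnings(as.integer(f[5])))) {
      stop(sprintf("malformed GTF line %d in %s: non-numeric coordinates", i, path),
           call. = FALSE)
    }
    if (!f[7] %in% c("+", "-")) {
      stop(sprintf("unknown strand character '%s' at GTF line %d in %s", f[7], i, path),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

collapse_biotype <- function(x) {
  dplyr::case_when(
    x == "protein_coding" ~ "coding",
    x %in% c("lncRNA", "antisense", "lincRNA") ~ "lncRNA",
    TRUE ~ "other"
  )
}

build_annotation_from_gr <- function(gr, biotype_filter = NULL) {
  mc <- S4Vectors::mcols(gr)
  if (is.null(mc$gene_id)) stop("GTF has no gene_id attribute", call. = FALSE)
  bt_raw <- if (!is.null(mc$gene_type)) as.character(mc$gene_type)
            else if (!is.null(mc$gene_biotype)) as.character(mc$gene_biotype)
            else rep(NA_character_, length(gr))
  type <- as.character(mc$type)
  is_gene <- type == "gene"
  is_exon <- type == "exon"

  gene_gr <- gr[is_gene]
  gid <- as.character(S4Vectors::mcols(gene_gr)$gene_id)
  if (anyDuplicated(gid)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  }
  if (any(as.character(GenomicRanges::strand(gene_gr)) == "*")) {
    stop("gene record with unknown strand", call. = FALSE)
  }

  exon_gr <- gr[is_exon]
  exon_gid <- as.character(S4Vectors::mcols(exon_gr)$gene_id)
  orphans <- setdiff(exon_gid, gid)
  if (length(orphans) > 0) {
    stop("exon records without a parent gene record: ",
         paste(utils::head(orphans, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(gid %in% exon_gid)) {
    missing_ex <- setdiff(gid, exon_gid)
    stop("gene records without any exon: ",
         paste(utils::head(missing_ex, 5), collapse = ", "), call. = FALSE)
  }

  # exon union per gene; order-invariant, duplicates collapse
  ex_by_gene <- GenomicRanges::reduce(
    GenomicRanges::split(GenomicRanges::granges(exon_gr), exon_gid)
  )
  ex_by_gene <- ex_by_gene[gid]
  mature_len <- vapply(IRanges::width(ex_by_gene), sum, integer(1))

  name_col <- S4Vectors::mcols(gene_gr)$gene_name
  genes <- tibble::tibble(
    gene_id = gid,
    gene_name = if (!is.null(name_col)) as.character(name_col) else gid,
    chrom = as.character(GenomicRanges::seqnames(gene_gr)),
    strand = as.character(GenomicRanges::strand(gene_gr)),
    start = GenomicRanges::start(gene_gr),
    end = GenomicRanges::end(gene_gr),
    biotype = collapse_biotype(bt_raw[is_gene]),
    n_exons = unname(lengths(ex_by_gene)),
    mature_length = unname(mature_len)
  )
  genes$gene_name[is.na(genes$gene_name)] <- genes$gene_id[is.na(genes$gene_name)]

  bad_span <- genes$mature_length > genes$end - genes$start + 1
  if (any(bad_span)) {
    stop("exon union exceeds gene span for: ",
         paste(utils::head(genes$gene_id[bad_span], 5), collapse = ", "),
         call. = FALSE)
  }

  if (!is.null(biotype_filter)) {
    keep <- genes$biotype %in% biotype_filter
    genes <- genes[keep, , drop = FALSE]
    ex_by_gene <- ex_by_gene[genes$gene_id]
  }

  exons_flat <- unlist(ex_by_gene, use.names = FALSE)
  S4Vectors::mcols(exons_flat)$gene_id <-
    rep(genes$gene_id, lengths(ex_by_gene))
  strand_rep <- rep(genes$strand, lengths(ex_by_gene))
  GenomicRanges::strand(exons_flat) <- strand_rep

  spans <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end), strand = genes$strand
  )
  names(spans) <- genes$gene_id

  genes <- dplyr::arrange(genes, .data$gene_id)
  structure(
    list(genes = genes, exons = exons_flat, spans = spans,
         .warned_chroms = new.env(parent = emptyenv())),
    class = "sclnc_annotation"
  )
}

#' Build an annotation object from tibbles
#'
#' Programmatic constructor used by the simulator and convenient for tests:
#' builds the same `sclnc_annotation` object as [read_gene_models()] from a
#' gene table and an exon table instead of a GTF file.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `strand` (`+`/`-`),
#'   `start`, `end`, `biotype` (`coding`/`lncRNA`/`other`), and optionally
#'   `gene_name`.
#' @param exons Tibble with columns `gene_id`, `start`, `end`. Every gene
#'   must have at least one exon inside its span.
#' @return An `sclnc_annotation` object.
#' @export
gene_models <- function(genes, exons) {
  genes <- tibble::as_tibble(genes)
  exons <- tibble::as_tibble(exons)
  if (!"gene_name" %in% names(genes)) genes$gene_name <- genes$gene_id
  bt_gtf <- c(coding = "protein_coding", lncRNA = "lncRNA", other = "misc_RNA")
  exons <- dplyr::left_join(
    exons, dplyr::select(genes, "gene_id", "chrom", "strand", "biotype", "gene_name"),
    by = "gene_id"
  )
  mk <- function(df, type) {
    GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
      type = type, gene_id = df$gene_id, gene_name = df$gene_name,
      gene_type = unname(bt_gtf[df$biotype])
    )
  }
  gr <- suppressWarnings(c(mk(genes, "gene"), mk(exons, "exon")))
  build_annotation_from_gr(gr)
}

#' Write an annotation back to GTF
#'
#' Emits one `gene` record and one `exon` record per exon-union interval for
#' every gene, with `gene_id`, `gene_name` and `gene_type` attributes, so
#' that re-reading with [read_gene_models()] reproduces the same gene models.
#'
#' @param ann An `sclnc_annotation` object.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "sclnc_annotation"))
  g <- ann$genes
  bt_gtf <- c(coding = "protein_coding", lncRNA = "lncRNA", other = "misc_RNA")
  attr_str <- function(id, name, bt) {
    sprintf('gene_id "%s"; gene_type "%s"; gene_name "%s";', id, bt_gtf[[bt]], name)
  }
  gene_lines <- sprintf("%s\tsclnc\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$chrom, g$start, g$end, g$strand,
                        mapply(attr_str, g$gene_id, g$gene_name, g$biotype))
  ex <- ann$exons
  ex_gid <- S4Vectors::mcols(ex)$gene_id
  gi <- match(ex_gid, g$gene_id)
  exon_lines <- sprintf("%s\tsclnc\texon\t%d\t%d\t.\t%s\t.\t%s",
                        as.character(GenomicRanges::seqnames(ex)),
                        GenomicRanges::start(ex), GenomicRanges::end(ex),
                        as.character(GenomicRanges::strand(ex)),
                        mapply(attr_str, g$gene_id[gi], g$gene_name[gi], g$biotype[gi]))
  ord <- order(g$chrom[gi], GenomicRanges::start(ex), method = "radix")
  writeLines(c(gene_lines[order(g$chrom, g$start, method = "radix")],
               exon_lines[ord]), path)
  invisible(path)
}

#' Query genes overlapping an interval
#'
#' Returns the `gene_id`s of all genes with at least `min_overlap` bp of
#' overlap with the 1-based inclusive query interval, either at the
#' exon-union level or at the gene-span level.
#'
#' @param ann An `sclnc_annotation` object.
#' @param chrom Chromosome name (no dialect normalisation is applied).
#' @param start,end 1-based inclusive query coordinates, `start <= end`.
#' @param level `"exon"` (exon-union intervals) or `"span"` (gene spans).
#' @return Character vector of gene ids (possibly empty), sorted.
#' @export
query_overlaps <- function(ann, chrom, start, end, level = c("exon", "span")) {
  stopifnot(inherits(ann, "sclnc_annotation"), start <= end)
  level <- match.arg(level)
  subj <- if (level == "exon") ann$exons else ann$spans
  if (!chrom %in% unique(as.character(GenomicRanges::seqnames(subj)))) {
    w <- ann$.warned_chroms
    if (is.null(w[[chrom]])) {
      message("query_overlaps: chromosome '", chrom, "' not in annotation")
      assign(chrom, TRUE, envir = w)
    }
    return(character(0))
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  hits <- GenomicRanges::findOverlaps(q, subj, ignore.strand = TRUE)
  ids <- if (level == "exon") {
    S4Vectors::mcols(subj)$gene_id[S4Vectors::subjectHits(hits)]
  } else {
    names(subj)[S4Vectors::subjectHits(hits)]
  }
  sort(unique(ids))
}

#' Subset an annotation by biotype
#'
#' @param ann An `sclnc_annotation` object.
#' @param biotypes Character vector of biotypes to keep.
#' @return An `sclnc_annotation` with only the selected genes.
#' @export
filter_biotype <- function(ann, biotypes) {
  stopifnot(inherits(ann, "sclnc_annotation"))
  keep <- ann$genes$biotype %in% biotypes
  genes <- ann$genes[keep, , drop = FALSE]
  ex_keep <- S4Vectors::mcols(ann$exons)$gene_id %in% genes$gene_id
  structure(
    list(genes = genes, exons = ann$exons[ex_keep],
         spans = ann$spans[names(ann$spans) %in% genes$gene_id],
         .warned_chroms = new.env(parent = emptyenv())),
    class = "sclnc_annotation"
  )
}

#' @export
print.sclnc_annotation <- function(x, ...) {
  tab <- table(x$genes$biotype)
  cat("<sclnc_annotation> ", nrow(x$genes), " genes on ",
      length(unique(x$genes$chrom)), " chromosome(s): ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method tidy sclnc_annotation
#' @export
tidy.sclnc_annotation <- function(x, ...) x$genes
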