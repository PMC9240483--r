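#' Build the oriented per-site table from raw four-sample calls
#'
#' This is the canonical container every downstream module consumes: one
#' row per biallelic (or retained multi-allelic) SNP with parent-oriented
#' bulk allele depths and per-base read counts. Orientation follows the
#' parental genotypes: the allele carried homozygously by the L parent is
#' the L allele, so `Laa`/`Saa` are the L-pool reads supporting the L- and
#' S-parent alleles, and `Lab`/`Sab` the same for the S-pool. Sites where a
#' parent is heterozygous, missing, or where the parents share an allele
#' are flagged `parent_uninformative` (not dropped; filtering is a later
#' stage).
#'
#' @param chrom,pos,ref,alt per-record fields; `alt` may be a comma-joined
#'   multi-allele string.
#' @param gt_parent_L,gt_parent_S parental genotype strings (`"0/0"` etc.).
#' @param ad_parent_L,ad_parent_S,ad_bulk_L,ad_bulk_S allele depths per
#'   sample: comma-joined strings (VCF `AD` style) or lists of integer
#'   vectors, one entry per REF/ALT allele. `"."`/`NA` is recorded as
#'   zero depth with `flag_missing_ad` set.
#' @return A data frame of class `bulk_sites` with columns: the raw fields
#'   above, `n_alt_alleles`, oriented depths `Laa`, `Saa`, `Lab`, `Sab`
#'   (`NA` when unoriented), per-base bulk depths `aa_A`..`aa_T`,
#'   `ab_A`..`ab_T`, bulk totals `depth_aa`, `depth_ab`, thresholded bulk
#'   genotype calls `call_aa`, `call_ab`, `orientation`
#'   (`"ok"`/`"parent_uninformative"`) and `flag_missing_ad`.
#' @export
bulk_site_table <- function(chrom, pos, ref, alt,
                            gt_parent_L, gt_parent_S,
                            ad_parent_L, ad_parent_S,
                            ad_bulk_L, ad_bulk_S) {
  n <- length(pos)
  as_ad_chr <- function(x) {
    if (is.list(x))
      vapply(x, function(v) paste(v, collapse = ","), "")
    else as.character(x)
  }
  ad_parent_L <- as_ad_chr(ad_parent_L)
  ad_parent_S <- as_ad_chr(ad_parent_S)
  ad_bulk_L <- as_ad_chr(ad_bulk_L)
  ad_bulk_S <- as_ad_chr(ad_bulk_S)
  stopifnot(
    length(chrom) == n, length(ref) == n, length(alt) == n,
    length(gt_parent_L) == n, length(gt_parent_S) == n,
    length(ad_parent_L) == n, length(ad_parent_S) == n,
    length(ad_bulk_L) == n, length(ad_bulk_S) == n
  )

  alt_split <- strsplit(as.character(alt), ",", fixed = TRUE)
  n_alt <- lengths(alt_split)

  parse_ad <- function(x, n_alleles, sample_label) {
    sp <- strsplit(x, ",", fixed = TRUE)
    missing <- is.na(x) | x == "." | x == ""
    out <- vector("list", n)
    for (i in seq_len(n)) {
      if (missing[i]) {
        out[[i]] <- integer(n_alleles[i])
      } else {
        v <- suppressWarnings(as.integer(sp[[i]]))
        if (anyNA(v) || length(v) != n_alleles[i])
          stop("malformed AD for sample ", sample_label, " at record ",
               chrom[i], ":", pos[i], " ('", x[i], "')")
        out[[i]] <- v
      }
    }
    list(ad = out, missing = missing)
  }
  n_alleles <- n_alt + 1L
  pL <- parse_ad(ad_parent_L, n_alleles, "parent_L")
  pS <- parse_ad(ad_parent_S, n_alleles, "parent_S")
  bL <- parse_ad(ad_bulk_L, n_alleles, "bulk_L")
  bS <- parse_ad(ad_bulk_S, n_alleles, "bulk_S")

  hom_allele <- function(gt) {
    # index (0-based) of the allele a sample carries homozygously, else NA
    a <- strsplit(gt, "[/|]")
    vapply(a, function(g) {
      if (length(g) == 2 && g[1] == g[2] && g[1] != ".")
        suppressWarnings(as.integer(g[1])) else NA_integer_
    }, 0L)
  }
  hL <- hom_allele(as.character(gt_parent_L))
  hS <- hom_allele(as.character(gt_parent_S))
  oriented <- !is.na(hL) & !is.na(hS) & hL != hS &
    hL <= n_alt & hS <= n_alt

  bases <- c("A", "C", "G", "T")
  bd_aa <- matrix(0L, n, 4, dimnames = list(NULL, bases))
  bd_ab <- matrix(0L, n, 4, dimnames = list(NULL, bases))
  Laa <- Saa <- Lab <- Sab <- rep(NA_integer_, n)
  call_aa <- call_ab <- rep(NA_character_, n)

  bulk_call <- function(ad) {
    tot <- sum(ad)
    if (tot == 0) return(NA_character_)
    major <- which.max(ad) - 1L
    if (ad[major + 1L] / tot >= 0.75) return(paste0(major, "/", major))
    second <- order(ad, decreasing = TRUE)[2] - 1L
    paste(sort(c(major, second)), collapse = "/")
  }

  for (i in seq_len(n)) {
    alleles <- c(ref[i], alt_split[[i]])
    known <- alleles %in% bases
    for (j in which(known)) {
      b <- alleles[j]
      bd_aa[i, b] <- bd_aa[i, b] + bL$ad[[i]][j]
      bd_ab[i, b] <- bd_ab[i, b] + bS$ad[[i]][j]
    }
    if (oriented[i]) {
      a <- hL[i] + 1L
      b <- hS[i] + 1L
      Laa[i] <- bL$ad[[i]][a]; Saa[i] <- bL$ad[[i]][b]
      Lab[i] <- bS$ad[[i]][a]; Sab[i] <- bS$ad[[i]][b]
    }
    call_aa[i] <- bulk_call(bL$ad[[i]])
    call_ab[i] <- bulk_call(bS$ad[[i]])
  }

  parent_pair <- function(p) {
    cbind(ref = vapply(p$ad, `[`, 0L, 1L),
          alt = vapply(p$ad, function(v) sum(v[-1]), 0L))
  }
  ppL <- parent_pair(pL)
  ppS <- parent_pair(pS)

  out <- data.frame(
    chrom = as.character(chrom), pos = as.integer(pos),
    ref = as.character(ref), alt = as.character(alt),
    n_alt_alleles = as.integer(n_alt),
    gt_parent_L = as.character(gt_parent_L),
    gt_parent_S = as.character(gt_parent_S),
    ad_parent_L = ad_parent_L, ad_parent_S = ad_parent_S,
    ad_bulk_L = ad_bulk_L, ad_bulk_S = ad_bulk_S,
    parent_L_ref = ppL[, "ref"], parent_L_alt = ppL[, "alt"],
    parent_S_ref = ppS[, "ref"], parent_S_alt = ppS[, "alt"],
    Laa = Laa, Saa = Saa, Lab = Lab, Sab = Sab,
    aa_A = bd_aa[, "A"], aa_C = bd_aa[, "C"],
    aa_G = bd_aa[, "G"], aa_T = bd_aa[, "T"],
    ab_A = bd_ab[, "A"], ab_C = bd_ab[, "C"],
    ab_G = bd_ab[, "G"], ab_T = bd_ab[, "T"],
    depth_aa = as.integer(rowSums(bd_aa)),
    depth_ab = as.integer(rowSums(bd_ab)),
    call_aa = call_aa, call_ab = call_ab,
    orientation = ifelse(oriented, "ok", "parent_uninformative"),
    flag_missing_ad = pL$missing | pS$missing | bL$missing | bS$missing,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bulk_sites", "data.frame")
  out
}

#' Read a four-sample BSA VCF into an oriented site table
#'
#' Loads a VCFv4.2 file with per-sample `AD` and maps its samples onto the
#' four experimental roles. Records whose alleles are not all single
#' nucleotides (indels, symbolic alleles) are dropped with a warning, since
#' the association statistics are SNP-only. Everything else is retained:
#' multi-allelic and parent-uninformative sites are flagged for the
#' filtering stage, not removed here.
#'
#' @param path VCF path.
#' @param sample_order named character vector mapping the roles
#'   `parent_L`, `parent_S`, `bulk_L`, `bulk_S` to sample names in the
#'   file.
#' @return A `bulk_sites` table (see [bulk_site_table()]).
#' @export
read_bulk_vcf <- function(path,
                          sample_order = c(parent_L = "parent_L",
                                           parent_S = "parent_S",
                                           bulk_L = "bulk_L",
                                           bulk_S = "bulk_S")) {
  roles <- c("parent_L", "parent_S", "bulk_L", "bulk_S")
  if (!all(roles %in% names(sample_order)))
    stop("sample_order must name all of: ", paste(roles, collapse = ", "))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) {
    return(bulk_site_table(character(0), integer(0), character(0),
                           character(0), character(0), character(0),
                           character(0), character(0), character(0),
                           character(0)))
  }
  have <- colnames(v@gt)[-1]
  missing <- setdiff(unname(sample_order[roles]), have)
  if (length(missing))
    stop("sample(s) absent from VCF: ", paste(missing, collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")

  keep_snp <- function(ref, alt) {
    alts <- strsplit(alt, ",", fixed = TRUE)
    nchar(ref) == 1 &
      vapply(alts, function(a) all(nchar(a) == 1) && !any(a %in% c("*", ".")),
             TRUE)
  }
  ok <- keep_snp(fix[, "REF"], fix[, "ALT"])
  if (any(!ok))
    warning(sum(!ok), " non-SNP record(s) dropped")
  idx <- which(ok)
  col <- function(mat, role) unname(mat[idx, sample_order[[role]]])
  bulk_site_table(
    chrom = fix[idx, "CHROM"], pos = as.integer(fix[idx, "POS"]),
    ref = fix[idx, "REF"], alt = fix[idx, "ALT"],
    gt_parent_L = col(gt, "parent_L"), gt_parent_S = col(gt, "parent_S"),
    ad_parent_L = col(ad, "parent_L"), ad_parent_S = col(ad, "parent_S"),
    ad_bulk_L = col(ad, "bulk_L"), ad_bulk_S = col(ad, "bulk_S")
  )
}

#' Read gene intervals from a GFF3 annotation
#'
#' Extracts `gene` features with their 1-based inclusive coordinates, for
#' per-region gene counting.
#'
#' @param gff_path GFF3 file path.
#' @return data frame with columns `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_intervals <- function(gff_path) {
  gr <- tryCatch(rtracklayer::import(gff_path, format = "gff3"),
                 error = function(e)
                   stop("failed to parse GFF3 '", gff_path, "': ",
                        conditionMessage(e)))
  if (length(gr) == 0 || !"type" %in% names(S4Vectors::mcols(gr))) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      stringsAsFactors = FALSE))
  }
  gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  md <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(md)) as.character(md$ID)
        else if ("Name" %in% names(md)) as.character(md$Name)
        else paste0("gene_", seq_along(gr))
  id[is.na(id)] <- paste0("gene_", which(is.na(id)))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             gene_id = id, stringsAsFactors = FALSE)
}

#' Write association regions as a 1-based TSV table
#'
#' Mirrors the reporting convention of BSA-seq studies: 1-based endpoint
#' positions on the window grid and lengths in Mb to two decimals.
#'
#' @param regions an `association_regions` data frame ([call_regions()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_tsv <- function(regions, path) {
  out <- data.frame(
    chrom = regions$chrom,
    start_bp = format(regions$start_bp, scientific = FALSE, trim = TRUE),
    end_bp = format(regions$end_bp, scientific = FALSE, trim = TRUE),
    length_mb = sprintf("%.2f", regions$length_mb),
    method = regions$method,
    peak_value = signif(regions$peak_value, 6),
    stringsAsFactors = FALSE
  )
  if (!is.null(regions$gene_count)) out$gene_count <- regions$gene_count
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write association regions as BED (0-based half-open)
#'
#' @inheritParams write_region_tsv
#' @return `path`, invisibly.
#' @export
write_region_bed <- function(regions, path) {
  bed <- data.frame(
    chrom = regions$chrom,
    start = format(pmax(regions$start_bp - 1, 0), scientific = FALSE,
                   trim = TRUE),
    end = format(regions$end_bp, scientific = FALSE, trim = TRUE),
    name = regions$method,
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
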