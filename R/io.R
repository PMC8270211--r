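# File formats, trio assembly, QC filters, locus clumping, pipeline.

# ---- trio panel container ---------------------------------------------------

.new_trio_panel <- function(variants, geno, ped) {
  stopifnot(is.matrix(geno), nrow(variants) == ncol(geno))
  structure(list(variants = variants, geno = geno, ped = ped),
            class = "trio_panel")
}

#' @export
print.trio_panel <- function(x, ...) {
  cat("Trio panel:", nrow(x$ped), "complete trios x",
      nrow(x$variants), "variants\n")
  if (!all(is.na(x$ped$subgroup)))
    print(table(subgroup = x$ped$subgroup))
  invisible(x)
}

.gt_to_dosage <- function(gt) {
  # hard-call GT strings -> ALT dosage; anything unparseable -> NA
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  out <- map[gt]
  dim(out) <- dim(gt); dimnames(out) <- dimnames(gt)
  out
}

#' Read case-parent trios from VCF + FAM
#'
#' Assembles complete trios from a VCF of hard genotype calls and a
#' PLINK-style FAM pedigree (columns: family, individual, father, mother,
#' sex, phenotype). Children whose two parents are both present in the
#' genotype file form the trios; children with an absent parent are
#' excluded with a warning. Multiallelic records are skipped with a
#' warning. Missing genotypes become `NA` and exclude that trio at that
#' variant only (handled at extraction time by [trios_for_variant()]).
#'
#' @param vcf_path VCF 4.x file with GT calls (biallelic SNPs used).
#' @param fam_path FAM pedigree file.
#' @param sidecar_path optional TSV with columns `individual` plus any of
#'   `subgroup`, `ethnicity`, `study`, matched to the children.
#' @return a `"trio_panel"`: list with `variants` (data.frame:
#'   `variant_id`, `chrom`, `pos`, `ref`, `alt`, `effect_allele`), `geno`
#'   (ALT-dosage matrix, samples x variants), `ped` (data.frame: `child`,
#'   `father`, `mother`, `sex_child`, `subgroup`, `ethnicity`, `study`).
#'   The effect allele defaults to ALT; see [set_effect_alleles()].
#' @export
read_trios <- function(vcf_path, fam_path, sidecar_path = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT)
  if (any(multi))
    warning(sum(multi), " multiallelic/invalid record(s) skipped")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(variant_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT, effect_allele = fix$ALT,
                         stringsAsFactors = FALSE)
  geno <- t(.gt_to_dosage(gt))          # samples x variants
  colnames(geno) <- variants$variant_id

  fam <- read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("family", "individual", "father",
                                  "mother", "sex", "phenotype"))
  is_child <- fam$father != "0" & fam$mother != "0"
  kids <- fam[is_child, , drop = FALSE]
  ok <- kids$individual %in% rownames(geno) &
    kids$father %in% rownames(geno) & kids$mother %in% rownames(geno)
  if (any(!ok))
    warning(sum(!ok), " child(ren) with missing member(s) excluded: ",
            paste(utils::head(kids$individual[!ok], 5), collapse = ", "))
  kids <- kids[ok, , drop = FALSE]
  ped <- data.frame(child = kids$individual, father = kids$father,
                    mother = kids$mother,
                    sex_child = ifelse(kids$sex == 2, 1L, 0L),
                    subgroup = NA_character_, ethnicity = NA_character_,
                    study = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(sidecar_path)) {
    sc <- read.table(sidecar_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    stopifnot("individual" %in% names(sc))
    idx <- match(ped$child, sc$individual)
    for (col in intersect(c("subgroup", "ethnicity", "study"), names(sc)))
      ped[[col]] <- sc[[col]][idx]
  }
  .new_trio_panel(variants, geno, ped)
}

#' Extract the trios at one variant
#'
#' Returns the trio data.frame for a single variant, coded as
#' effect-allele dosages (flipped from ALT dosage when the effect allele
#' is REF). Trios with a missing genotype in any member at this variant
#' are dropped ("complete trios only").
#'
#' @param panel a `"trio_panel"`.
#' @param variant_id variant identifier.
#' @param subgroup optional subgroup label to subset trios.
#' @return a data.frame with `g_child`, `g_mother`, `g_father`,
#'   `sex_child`, `subgroup`, `ethnicity`.
#' @export
trios_for_variant <- function(panel, variant_id, subgroup = NULL) {
  stopifnot(inherits(panel, "trio_panel"))
  j <- match(variant_id, panel$variants$variant_id)
  if (is.na(j)) stop("unknown variant: ", variant_id)
  ped <- panel$ped
  if (!is.null(subgroup)) ped <- ped[ped$subgroup %in% subgroup, , drop = FALSE]
  g <- panel$geno[, j]
  d <- data.frame(g_child = g[ped$child], g_mother = g[ped$mother],
                  g_father = g[ped$father], sex_child = ped$sex_child,
                  subgroup = ped$subgroup, ethnicity = ped$ethnicity,
                  stringsAsFactors = FALSE, row.names = NULL)
  d <- d[complete.cases(d[c("g_child", "g_mother", "g_father")]), ,
         drop = FALSE]
  if (panel$variants$effect_allele[j] == panel$variants$ref[j]) {
    d$g_child <- 2L - d$g_child
    d$g_mother <- 2L - d$g_mother
    d$g_father <- 2L - d$g_father
  }
  d
}

#' Set the effect allele from founder minor alleles
#'
#' Sets each variant's effect allele to its minor allele among the
#' founders (parents) of a reference cohort — by convention the
#' first-configured subgroup/study — so that one allele convention applies
#' across all subgroups and studies.
#'
#' @param panel a `"trio_panel"` (defines the variants to update).
#' @param reference_panel panel whose founders define the minor allele
#'   (defaults to `panel` itself).
#' @param subgroup optional subgroup of the reference panel.
#' @return `panel` with updated `variants$effect_allele`.
#' @export
set_effect_alleles <- function(panel, reference_panel = panel,
                               subgroup = NULL) {
  stopifnot(inherits(panel, "trio_panel"),
            inherits(reference_panel, "trio_panel"))
  ped <- reference_panel$ped
  if (!is.null(subgroup)) ped <- ped[ped$subgroup %in% subgroup, , drop = FALSE]
  founders <- unique(c(ped$father, ped$mother))
  idx <- match(panel$variants$variant_id, reference_panel$variants$variant_id)
  g <- reference_panel$geno[founders, , drop = FALSE]
  alt_freq <- colMeans(g, na.rm = TRUE)[idx] / 2
  minor_is_ref <- !is.na(alt_freq) & alt_freq > 0.5
  ea <- panel$variants$alt
  ea[minor_is_ref] <- panel$variants$ref[minor_is_ref]
  panel$variants$effect_allele <- ea
  panel
}

#' Filter variants on founder minor-allele frequency
#'
#' Retains variants whose MAF among founders is at least `min_maf`
#' (inclusive), the standard common-variant analysis filter.
#'
#' @param panel a `"trio_panel"`.
#' @param min_maf minimum founder MAF (default 0.05).
#' @return the filtered panel.
#' @export
filter_founder_maf <- function(panel, min_maf = 0.05) {
  stopifnot(inherits(panel, "trio_panel"), min_maf >= 0, min_maf <= 0.5)
  founders <- unique(c(panel$ped$father, panel$ped$mother))
  g <- panel$geno[founders, , drop = FALSE]
  f <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= min_maf
  panel$variants <- panel$variants[keep, , drop = FALSE]
  panel$geno <- panel$geno[, keep, drop = FALSE]
  panel
}

# ---- VCF/FAM export ---------------------------------------------------------

#' Write a trio panel as VCF + FAM
#'
#' Minimal VCF 4.2 with GT-only genotypes plus the matching FAM pedigree,
#' suitable for end-to-end pipeline tests and interchange.
#'
#' @param panel a `"trio_panel"`.
#' @param vcf_path,fam_path output paths.
#' @return invisibly, `vcf_path`.
#' @export
write_trio_vcf <- function(panel, vcf_path, fam_path) {
  stopifnot(inherits(panel, "trio_panel"))
  v <- panel$variants
  samples <- rownames(panel$geno)
  gt_str <- c("0/0", "0/1", "1/1")[panel$geno + 1L]    # NA stays NA
  gt_str[is.na(gt_str)] <- "./."
  dim(gt_str) <- dim(panel$geno)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j) {
    paste(c(v$chrom[j], v$pos[j], v$variant_id[j], v$ref[j], v$alt[j],
            ".", "PASS", ".", "GT", gt_str[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), vcf_path)
  ped <- panel$ped
  fam <- rbind(
    data.frame(family = ped$child, individual = ped$child,
               father = ped$father, mother = ped$mother,
               sex = ifelse(ped$sex_child == 1L, 2L, 1L), phenotype = 2L),
    data.frame(family = ped$child, individual = ped$father,
               father = "0", mother = "0", sex = 1L, phenotype = 0L),
    data.frame(family = ped$child, individual = ped$mother,
               father = "0", mother = "0", sex = 2L, phenotype = 0L))
  write.table(fam, fam_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(vcf_path)
}

#' Simulate a genotype-level trio panel
#'
#' Full trio-level companion to [simulate_null_panel()]: draws ascertained
#' trios per variant (via [simulate_trios()]) and assembles them into a
#' `"trio_panel"` with explicit sample ids, ready for [write_trio_vcf()]
#' or [run_pipeline()].
#'
#' @param n_trios number of trios.
#' @param n_variants number of independent variants.
#' @param maf effect-allele frequency, scalar or per-variant vector.
#' @param rr relative risk, scalar or per-variant vector.
#' @param seed optional integer seed.
#' @param subgroup,study labels stored in the pedigree.
#' @param chrom,pos0 chromosome label and starting position (variants are
#'   placed 1 Mb apart).
#' @param id_prefix prefix for sample ids.
#' @return a `"trio_panel"`.
#' @export
simulate_trio_panel <- function(n_trios, n_variants, maf, rr = 1, seed = NULL,
                                subgroup = NA_character_,
                                study = NA_character_,
                                chrom = "1", pos0 = 1e6L,
                                id_prefix = "trio") {
  if (!is.null(seed)) set.seed(seed)
  maf <- rep_len(maf, n_variants)
  rr <- rep_len(rr, n_variants)
  geno <- matrix(NA_integer_, nrow = 3L * n_trios, ncol = n_variants)
  child <- sprintf("%s%04d_c", id_prefix, seq_len(n_trios))
  father <- sprintf("%s%04d_f", id_prefix, seq_len(n_trios))
  mother <- sprintf("%s%04d_m", id_prefix, seq_len(n_trios))
  rownames(geno) <- c(child, father, mother)
  sex <- rbinom(n_trios, 1L, 0.5)
  for (j in seq_len(n_variants)) {
    tr <- simulate_trios(n_trios, maf[j], rr[j])
    geno[child, j] <- tr$g_child
    geno[father, j] <- tr$g_father
    geno[mother, j] <- tr$g_mother
  }
  variants <- data.frame(
    variant_id = sprintf("snp%05d", seq_len(n_variants)),
    chrom = chrom, pos = as.integer(pos0 + (seq_len(n_variants) - 1L) * 1e6),
    ref = "A", alt = "G", effect_allele = "G", stringsAsFactors = FALSE)
  colnames(geno) <- variants$variant_id
  ped <- data.frame(child = child, father = father, mother = mother,
                    sex_child = sex, subgroup = subgroup,
                    ethnicity = NA_character_, study = study,
                    stringsAsFactors = FALSE)
  .new_trio_panel(variants, geno, ped)
}

# ---- summary-statistic TSV dialect -----------------------------------------

#' Write / read per-variant summary statistics
#'
#' Tab-separated with columns `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `beta`, `se`, `z`, `p`, `n_informative` (plus any
#' extra columns present). Metadata (e.g. fitted model variances) are
#' stored as leading `#key=value` comment lines. Numeric columns are
#' written at full double precision, so a write/read round trip is
#' lossless to >= 15 significant digits.
#'
#' @param sumstats data.frame of summary statistics.
#' @param path file path.
#' @param metadata named list/vector written as `#key=value` lines.
#' @return `write_sumstats()` returns `path` invisibly; `read_sumstats()`
#'   the data.frame with metadata in attribute `"metadata"`.
#' @export
write_sumstats <- function(sumstats, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(metadata))
    writeLines(paste0("#", names(metadata), "=",
                      vapply(metadata, function(v) sprintf("%.17g", as.numeric(v)),
                             character(1))), con)
  out <- sumstats
  for (nm in names(out))
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- NULL
  if (length(meta_lines)) {
    kv <- sub("^#", "", lines[meta_lines])
    meta <- as.list(as.numeric(sub("^[^=]*=", "", kv)))
    names(meta) <- sub("=.*$", "", kv)
  }
  df <- read.table(text = lines[setdiff(seq_along(lines), meta_lines)],
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}

# ---- locus clumping ---------------------------------------------------------

.ld_lookup <- function(ld, id1, id2, missing_ld) {
  if (is.null(ld)) r2 <- NA_real_
  else if (is.function(ld)) r2 <- ld(id1, id2)
  else if (is.matrix(ld)) {
    r2 <- if (id1 %in% rownames(ld) && id2 %in% colnames(ld))
      ld[id1, id2] else NA_real_
  } else stop("'ld' must be NULL, a matrix with dimnames, or a function")
  if (is.na(r2)) {
    if (missing_ld == "error")
      stop("missing LD for pair ", id1, " / ", id2)
    r2 <- 0
  }
  r2
}

#' Greedy distance/LD clumping of significant variants into loci
#'
#' Repeatedly takes the most significant unassigned variant below
#' `p_threshold` as an index, assigns to its locus every unassigned
#' variant (significant or not among the significant set) within
#' `radius_bp` on the same chromosome and with LD `r^2 > r2_threshold`
#' with the index, and repeats until no significant variant remains
#' unassigned. The result partitions the significant set; bounds are
#' defined by member positions.
#'
#' @param sumstats data.frame with `variant_id`, `chrom`, `pos`, `p`.
#' @param ld pairwise r-squared source: a matrix with variant ids as
#'   dimnames, a function `(id1, id2) -> r2`, or `NULL` (all missing).
#' @param p_threshold significance threshold defining clump-able variants
#'   (default 1e-6, the suggestive level).
#' @param radius_bp half-width of the clumping window (default 500 kb;
#'   the window is `[pos - radius_bp, pos + radius_bp]` inclusive).
#' @param r2_threshold LD threshold (strict `>`; default 0.2).
#' @param missing_ld `"zero"` (treat a missing pair as r2 = 0, with one
#'   warning) or `"error"`.
#' @return a list of loci; each locus is a list with `index_id`,
#'   `members`, `chrom`, `start`, `end`, `index_p`.
#' @export
clump_loci <- function(sumstats, ld = NULL, p_threshold = 1e-6,
                       radius_bp = 5e5, r2_threshold = 0.2,
                       missing_ld = c("zero", "error")) {
  missing_ld <- match.arg(missing_ld)
  stopifnot(all(c("variant_id", "chrom", "pos", "p") %in% names(sumstats)))
  sig <- sumstats[sumstats$p < p_threshold, , drop = FALSE]
  sig <- sig[order(sig$p), , drop = FALSE]
  if (is.null(ld) && nrow(sig) > 1L && missing_ld == "zero")
    warning("no LD source supplied; treating all pairwise r2 as 0")
  assigned <- character(0)
  loci <- list()
  while (nrow(sig) > 0L) {
    idx <- sig[1L, ]
    cand <- sig[-1L, , drop = FALSE]
    cand <- cand[cand$chrom == idx$chrom &
                   abs(cand$pos - idx$pos) <= radius_bp, , drop = FALSE]
    in_ld <- vapply(cand$variant_id, function(id)
      .ld_lookup(ld, idx$variant_id, id, missing_ld) > r2_threshold,
      logical(1))
    members <- c(idx$variant_id, cand$variant_id[in_ld])
    pos <- sumstats$pos[match(members, sumstats$variant_id)]
    loci[[length(loci) + 1L]] <- list(
      index_id = idx$variant_id, members = members,
      chrom = idx$chrom, start = min(pos), end = max(pos),
      index_p = idx$p)
    sig <- sig[!sig$variant_id %in% members, , drop = FALSE]
  }
  loci
}

# ---- end-to-end pipeline ----------------------------------------------------

.panel_sumstats <- function(panel, subgroup, max_mendel_rate = 0.05) {
  v <- panel$variants
  rows <- lapply(seq_len(nrow(v)), function(j) {
    tr <- trios_for_variant(panel, v$variant_id[j], subgroup = subgroup)
    mf <- mendelian_filter(tr)
    if (mf$violation_rate > max_mendel_rate) return(NULL)
    s <- gtdt_additive(mf$trios, effect_allele = v$effect_allele[j])
    data.frame(variant_id = v$variant_id[j], chrom = v$chrom[j],
               pos = v$pos[j], effect_allele = v$effect_allele[j],
               beta = s$beta, se = s$se, z = s$z, p = s$p,
               n_informative = s$n_informative, status = s$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.meta_across_studies <- function(tabs) {
  all_ids <- unique(unlist(lapply(tabs, `[[`, "variant_id")))
  rows <- lapply(all_ids, function(id) {
    per <- lapply(tabs, function(tb) tb[tb$variant_id == id & tb$status == "ok", ,
                                        drop = FALSE])
    per <- per[vapply(per, nrow, 0L) > 0L]
    if (!length(per)) return(NULL)
    stats <- lapply(per, function(tb)
      .gtdt_stat(tb$beta, tb$se, tb$z, tb$p, tb$n_informative,
                 NA_integer_, NA_integer_, "ok", tb$effect_allele))
    m <- ivw_meta(stats)
    first <- per[[1]]
    data.frame(variant_id = id, chrom = first$chrom, pos = first$pos,
               effect_allele = first$effect_allele,
               beta = m$beta, se = m$se, z = m$z, p = m$p,
               k_studies = m$k_studies, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full trio overlap pipeline
#'
#' Chains: read (or simulate) trio panels for each study -> per-variant
#' Mendelian screen and founder-MAF filter -> per-study, per-subgroup
#' additive gTDT -> inverse-variance meta-analysis across studies within
#' subgroup -> composite-null product test across subgroups. Per-stage
#' TSVs and a run log are written to `out_dir`.
#'
#' `config` is a list with either
#' * `studies`: a named list, each element a list with `vcf`, `fam` and
#'   optionally `sidecar` paths (the sidecar supplies `subgroup` labels);
#'   or
#' * `simulate`: a list with `n_variants`, `maf`, and per-study trio
#'   counts `n1`, `n2` (smoke-scale genotype-level simulation; all
#'   variants null unless `rr1`/`rr2` given).
#'
#' plus optional `subgroups` (two labels; default the two observed),
#' `min_maf` (default 0.05) and `p_screen` (default 1e-4).
#'
#' @param config configuration list (above).
#' @param out_dir output directory (created if needed).
#' @param seed optional integer seed (simulation mode).
#' @return invisibly, a list with the per-subgroup meta tables, the
#'   overlap-test table and the fitted composite-null model.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  min_maf <- config$min_maf %||% 0.05
  p_screen <- config$p_screen %||% 1e-4

  if (!is.null(config$simulate)) {
    if (!is.null(seed)) set.seed(seed)
    sc <- config$simulate
    rr1 <- sc$rr1 %||% 1; rr2 <- sc$rr2 %||% 1
    panels <- list(
      study1 = .sim_study_panel(sc, rr1, rr2, "st1"),
      study2 = .sim_study_panel(sc, rr1, rr2, "st2"))
  } else if (!is.null(config$studies)) {
    panels <- lapply(config$studies, function(st)
      read_trios(st$vcf, st$fam, st$sidecar))
  } else stop("config must contain either 'studies' or 'simulate'")

  subgroups <- config$subgroups %||%
    sort(unique(stats::na.omit(unlist(lapply(panels, function(p) p$ped$subgroup)))))
  if (length(subgroups) != 2L)
    stop("exactly two subgroups required; found: ",
         paste(subgroups, collapse = ", "))
  if (identical(subgroups[1], subgroups[2]))
    warning("the two subgroups are identical; independence of the two ",
            "Z panels is violated and overlap p-values are meaningless")

  # one allele convention: minor allele among founders of the first
  # study's first subgroup
  ref_panel <- panels[[1]]
  panels <- lapply(panels, set_effect_alleles,
                   reference_panel = ref_panel, subgroup = subgroups[1])
  panels <- lapply(panels, filter_founder_maf, min_maf = min_maf)

  tabs <- list()
  for (st in names(panels)) {
    for (sg in subgroups) {
      tab <- .panel_sumstats(panels[[st]], sg)
      write_sumstats(tab, file.path(out_dir, paste0("gtdt_", st, "_", sg, ".tsv")))
      tabs[[paste(st, sg, sep = ".")]] <- tab
    }
  }
  meta <- lapply(subgroups, function(sg)
    .meta_across_studies(tabs[grepl(paste0("\\.", sg, "$"), names(tabs))]))
  names(meta) <- subgroups
  for (sg in subgroups)
    write_sumstats(meta[[sg]], file.path(out_dir, paste0("meta_", sg, ".tsv")))

  common <- intersect(meta[[1]]$variant_id, meta[[2]]$variant_id)
  message(length(common), " variant(s) present in both subgroups used for overlap test")
  m1 <- meta[[1]][match(common, meta[[1]]$variant_id), ]
  m2 <- meta[[2]][match(common, meta[[2]]$variant_id), ]
  fit <- placo_genomewide(m1$z, m2$z, p_screen = p_screen)
  overlap <- data.frame(variant_id = common, chrom = m1$chrom, pos = m1$pos,
                        effect_allele = m1$effect_allele,
                        z1 = m1$z, z2 = m2$z,
                        t_placo = fit$stats$t, p_placo = fit$stats$p,
                        stringsAsFactors = FALSE)
  write_sumstats(overlap, file.path(out_dir, "placo.tsv"),
                 metadata = list(var_z1 = fit$model$var_z1,
                                 var_z2 = fit$model$var_z2,
                                 p_screen = p_screen))
  writeLines(c(paste0("trioverlap ", as.character(utils::packageVersion("trioverlap"))),
               paste0("seed: ", if (is.null(seed)) "none" else seed),
               paste0("date: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
               paste0("config: ", paste(deparse(config), collapse = " "))),
             file.path(out_dir, "run_log.txt"))
  invisible(list(meta = meta, overlap = overlap, model = fit$model))
}

.sim_study_panel <- function(sc, rr1, rr2, prefix) {
  nv <- sc$n_variants
  p1 <- simulate_trio_panel(sc$n1, nv, sc$maf, rr1,
                            subgroup = "sub1", id_prefix = paste0(prefix, "a"))
  p2 <- simulate_trio_panel(sc$n2, nv, sc$maf, rr2,
                            subgroup = "sub2", id_prefix = paste0(prefix, "b"))
  .new_trio_panel(p1$variants, rbind(p1$geno, p2$geno), rbind(p1$ped, p2$ped))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
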