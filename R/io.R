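# Plain-text interchange: TSV dialects for subjects, edge strengths and
# genotypes; PED/MAP; optional NIfTI export of voxel maps.

# TSV with '#'-prefixed header lines recording provenance (version, config
# hash, seed); readable back with read_tsv().
write_tsv <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, meta[[nm]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write / read the long-format edge-strength table
#'
#' Columns: subject, node1, node2, strength — one row per subject per edge.
#'
#' @param conn a \code{"connectivity"} object.
#' @param path output file.
#' @param meta optional named list written as '#' header lines.
#' @export
write_strengths_tsv <- function(conn, path, meta = NULL) {
  stopifnot(inherits(conn, "connectivity"))
  s <- conn$strengths
  parts <- do.call(rbind, strsplit(colnames(s), "--", fixed = TRUE))
  long <- data.frame(
    subject = rep(rownames(s), times = ncol(s)),
    node1 = rep(parts[, 1], each = nrow(s)),
    node2 = rep(parts[, 2], each = nrow(s)),
    strength = as.vector(s), stringsAsFactors = FALSE)
  write_tsv(long, path, meta)
}

#' @rdname write_strengths_tsv
#' @return \code{read_strengths_tsv} returns a subjects x edges matrix.
#' @export
read_strengths_tsv <- function(path) {
  long <- read_tsv(path)
  long$edge <- edge_id(long$node1, long$node2)
  subs <- unique(long$subject); eds <- sort(unique(long$edge))
  m <- matrix(NA_real_, length(subs), length(eds),
              dimnames = list(subs, eds))
  m[cbind(match(long$subject, subs), match(long$edge, eds))] <- long$strength
  m
}

#' Write / read genotypes in the simple TSV dialect
#'
#' Columns: subject, snp, allele1, allele2; missing genotypes coded
#' \code{0 0}.
#'
#' @param table a [genotype_table()].
#' @param path output file.
#' @param meta optional '#' header lines.
#' @export
write_genotypes_tsv <- function(table, path, meta = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  g <- table$geno
  al <- ifelse(is.na(g), "0/0", g)
  parts <- do.call(rbind, strsplit(as.vector(al), "/", fixed = TRUE))
  long <- data.frame(subject = rep(rownames(g), times = ncol(g)),
                     snp = rep(colnames(g), each = nrow(g)),
                     allele1 = parts[, 1], allele2 = parts[, 2],
                     stringsAsFactors = FALSE)
  write_tsv(long, path, meta)
}

#' @rdname write_genotypes_tsv
#' @param snps optional SNP metadata (id, allele1, allele2, risk); when
#'   omitted the two alleles are inferred from the data and the rarer one is
#'   taken as the risk allele.
#' @export
read_genotypes_tsv <- function(path, snps = NULL) {
  long <- read_tsv(path)
  long$allele1 <- as.character(long$allele1)
  long$allele2 <- as.character(long$allele2)
  build_genotype_table(long, snps)
}

build_genotype_table <- function(long, snps = NULL) {
  subs <- unique(long$subject); snp_ids <- unique(long$snp)
  miss <- long$allele1 == "0" | long$allele2 == "0"
  gstr <- ifelse(miss, NA_character_,
                 ifelse(long$allele1 <= long$allele2,
                        paste(long$allele1, long$allele2, sep = "/"),
                        paste(long$allele2, long$allele1, sep = "/")))
  g <- matrix(NA_character_, length(subs), length(snp_ids),
              dimnames = list(subs, snp_ids))
  g[cbind(match(long$subject, subs), match(long$snp, snp_ids))] <- gstr
  if (is.null(snps)) {
    snps <- do.call(rbind, lapply(snp_ids, function(s) {
      al <- c(long$allele1[long$snp == s], long$allele2[long$snp == s])
      al <- sort(unique(al[al != "0"]))
      if (length(al) == 1) al <- c(al, al)
      cnt <- table(factor(c(long$allele1[long$snp == s],
                            long$allele2[long$snp == s]), levels = al))
      data.frame(id = s, allele1 = al[1], allele2 = al[2],
                 risk = names(cnt)[which.min(cnt)], stringsAsFactors = FALSE)
    }))
  }
  genotype_table(g[, snps$id, drop = FALSE], snps)
}

#' Write / read genotypes as a PED/MAP pair
#'
#' PED: FID IID PAT MAT SEX PHENO then two allele columns per SNP (missing
#' \code{0 0}); phenotype is 2 for HA, 1 otherwise. MAP: chr, snp id, cM,
#' position (all positional fields 0: no physical map is simulated).
#'
#' @param table a [genotype_table()].
#' @param prefix output path prefix; writes \code{<prefix>.ped} and
#'   \code{<prefix>.map}.
#' @param groups optional per-subject group labels for the phenotype column.
#' @export
write_ped_map <- function(table, prefix, groups = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  g <- table$geno
  n <- nrow(g)
  pheno <- if (is.null(groups)) rep(0, n) else ifelse(groups == "HA", 2, 1)
  allele_cols <- lapply(seq_len(ncol(g)), function(k) {
    a <- ifelse(is.na(g[, k]), "0/0", g[, k])
    do.call(rbind, strsplit(a, "/", fixed = TRUE))
  })
  ped <- cbind(rownames(g), rownames(g), 0, 0, 0, pheno,
               do.call(cbind, allele_cols))
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  map <- data.frame(chr = 0, snp = colnames(g), cm = 0, pos = 0)
  utils::write.table(map, paste0(prefix, ".map"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_ped_map
#' @param ped,map paths to the PED and MAP files.
#' @param snps optional SNP metadata as in [read_genotypes_tsv()].
#' @export
read_ped_map <- function(ped, map, snps = NULL) {
  mp <- utils::read.table(map, stringsAsFactors = FALSE)
  pd <- utils::read.table(ped, stringsAsFactors = FALSE,
                          colClasses = "character")
  snp_ids <- mp[[2]]
  stopifnot(ncol(pd) == 6 + 2 * length(snp_ids))
  long <- do.call(rbind, lapply(seq_along(snp_ids), function(k) {
    data.frame(subject = pd[[2]], snp = snp_ids[k],
               allele1 = pd[[6 + 2 * k - 1]], allele2 = pd[[6 + 2 * k]],
               stringsAsFactors = FALSE)
  }))
  build_genotype_table(long, snps)
}

#' Write a labelled square matrix as TSV
#' @param m matrix with dimnames.
#' @param path output file.
#' @param meta optional '#' header lines.
#' @export
write_matrix_tsv <- function(m, path, meta = NULL) {
  df <- data.frame(node = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, meta)
}

#' Export per-subject voxel maps as NIfTI files
#'
#' One file per subject; requires the RNifti package.
#'
#' @param maps subjects x voxels matrix.
#' @param grid_shape 3-D grid dimensions.
#' @param dir output directory.
#' @param prefix filename prefix (e.g. \code{"fa"}).
#' @export
write_nifti_maps <- function(maps, grid_shape, dir, prefix = "map") {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI export requires the RNifti package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in rownames(maps)) {
    arr <- array(maps[s, ], dim = grid_shape)
    RNifti::writeNifti(RNifti::asNifti(arr),
                       file.path(dir, sprintf("%s_%s.nii.gz", prefix, s)))
  }
  invisible(dir)
}
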