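#' Read an F2 cross from delimited files
#'
#' Expects three comma-delimited files:
#' * the genetic map with header `chrom,marker,pos_cM`, optionally preceded
#'   by a `# design: achiasmate|chiasmate` comment line (mandatory for
#'   files written by [write_cross()]);
#' * the genotype matrix, one row per individual, one column per marker
#'   (same order as the map), cells in `{2,1,0,NA}`;
#' * the phenotype table with header `id,sex,y`.
#'
#' @param map_path,geno_path,pheno_path File paths.
#' @param design Meiosis design; overrides the map-file tag if given.
#' @return A [cross_pop()].
#' @export
read_cross <- function(map_path, geno_path, pheno_path, design = NULL) {
  for (p in c(map_path, geno_path, pheno_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
  }
  first <- readLines(map_path, n = 1)
  if (is.null(design)) {
    m <- regmatches(first, regexec("#\\s*design:\\s*(achiasmate|chiasmate)", first))[[1]]
    design <- if (length(m) == 2) m[2] else "achiasmate"
  }
  map_df <- utils::read.csv(map_path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("chrom", "marker", "pos_cM") %in% names(map_df))) {
    stop("map file must have header chrom,marker,pos_cM", call. = FALSE)
  }
  map <- genetic_map(map_df$chrom, map_df$marker, map_df$pos_cM)

  geno <- utils::read.csv(geno_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(colnames(geno), map$marker)) {
    stop("genotype matrix columns do not match the map's markers", call. = FALSE)
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"

  ph <- utils::read.csv(pheno_path, stringsAsFactors = FALSE)
  if (!all(c("id", "sex", "y") %in% names(ph))) {
    stop("phenotype file must have header id,sex,y", call. = FALSE)
  }
  if (any(is.na(suppressWarnings(as.numeric(ph$y))))) {
    stop("non-numeric phenotype value in phenotype file", call. = FALSE)
  }
  sx <- ph$sex
  if (!all(sx %in% c(1, 2))) {
    lev <- sort(unique(sx))
    if (length(lev) != 2) stop("sex must have exactly two levels", call. = FALSE)
    sx <- match(sx, lev)
  }
  cross_pop(map, geno, sx, as.numeric(ph$y), design = design)
}

#' Write an F2 cross to delimited files
#'
#' Writes the map, genotype and phenotype files read back by [read_cross()],
#' plus (when present) a `truth.json` file recording the simulation truth.
#'
#' @param pop A [cross_pop()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cross <- function(pop, dir, prefix = "cross") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(map = file.path(dir, paste0(prefix, "_map.csv")),
             geno = file.path(dir, paste0(prefix, "_geno.csv")),
             pheno = file.path(dir, paste0(prefix, "_pheno.csv")))
  con <- file(paths["map"], "w")
  writeLines(sprintf("# design: %s", pop$design), con)
  utils::write.csv(as.data.frame(pop$map), con, row.names = FALSE, quote = FALSE)
  close(con)
  utils::write.csv(as.data.frame(pop$geno), paths["geno"], row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(id = seq_along(pop$y), sex = pop$sex, y = pop$y),
                   paths["pheno"], row.names = FALSE, quote = FALSE)
  if (!is.null(pop$truth)) {
    paths <- c(paths, truth = file.path(dir, paste0(prefix, "_truth.json")))
    tr <- pop$truth
    out <- list(seed = tr$seed,
                qtl_geno = tr$qtl_geno,
                effects = tr$effects,
                qtls = tr$cfg$qtls,
                epistases = tr$cfg$epistases,
                mu = tr$cfg$mu, var_e = tr$cfg$var_e,
                design = tr$cfg$design)
    jsonlite::write_json(out, paths["truth"], auto_unbox = TRUE, digits = NA,
                         na = "null")
  }
  invisible(paths)
}
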