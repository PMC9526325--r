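# Plain-text import/export: PLINK-style PED/MAP, phenotype/covariate TSV,
# posterior-liability-table cache, and formatted power tables.

# association functions accept either a PhenotypeSet or a plain data.frame
# with at least individual_id and Z (e.g. from readPhenotypes())
.phenoData <- function(x) {
  if (is.data.frame(x)) x else phenotypes(x)
}

#' Export a cohort as PLINK-style PED/MAP files
#'
#' Writes `<prefix>.ped` (family id, individual id, paternal id, maternal
#' id, sex with PLINK coding 1 = male / 2 = female, phenotype 1 = control /
#' 2 = case / -9 missing, then two allele columns per variant coded 1 =
#' major, 2 = minor) and `<prefix>.map` (chromosome 1, variant id, 0,
#' index position).
#'
#' @param cohort a [FamCohort-class].
#' @param genoTable a [GenotypeTable-class].
#' @param phenos optional [PhenotypeSet-class] (or data.frame) supplying
#'   case-control status.
#' @param prefix output path prefix.
#' @return invisibly, the two file paths.
#' @export
writePed <- function(cohort, genoTable, phenos = NULL, prefix) {
  m <- members(cohort)
  G <- genotypes(genoTable)[as.character(m$individual_id), , drop = FALSE]
  z <- rep(-9L, nrow(m))
  if (!is.null(phenos)) {
    d <- .phenoData(phenos)
    zi <- d$Z[match(m$individual_id, d$individual_id)]
    z <- ifelse(is.na(zi), -9L, zi + 1L)
  }
  a1 <- ifelse(G >= 1L, 2L, 1L)   # first allele carries the first minor copy
  a2 <- ifelse(G == 2L, 2L, 1L)
  alleles <- matrix(0L, nrow(G), 2L * ncol(G))
  alleles[, seq(1L, 2L * ncol(G), 2L)] <- a1
  alleles[, seq(2L, 2L * ncol(G), 2L)] <- a2
  ped <- cbind(m$family_id, m$individual_id,
               ifelse(is.na(m$father_id), 0L, m$father_id),
               ifelse(is.na(m$mother_id), 0L, m$mother_id),
               ifelse(m$sex == 0L, 1L, 2L), z, alleles)
  pedPath <- paste0(prefix, ".ped")
  mapPath <- paste0(prefix, ".map")
  write.table(ped, pedPath, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  vi <- variantInfo(genoTable)
  write.table(data.frame(1L, vi$variant_id, 0L, seq_len(nrow(vi))),
              mapPath, quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(ped = pedPath, map = mapPath))
}

# role inference from pedigree links alone
.inferRoles <- function(m) {
  isParentOf <- m$individual_id %in% c(m$father_id, m$mother_id)
  gen <- integer(nrow(m))              # founders 0, then by parental depth
  repeat {
    newGen <- ifelse(is.na(m$father_id), 0L,
                     pmax(gen[match(m$father_id, m$individual_id)],
                          gen[match(m$mother_id, m$individual_id)],
                          na.rm = TRUE) + 1L)
    newGen[is.na(newGen)] <- 0L
    if (identical(newGen, gen)) break
    gen <- newGen
  }
  role <- rep(NA_character_, nrow(m))
  leaf <- !isParentOf
  role[leaf] <- "offspring"
  pf <- match(m$father_id[leaf], m$individual_id)
  pm <- match(m$mother_id[leaf], m$individual_id)
  role[unique(pf[!is.na(pf)])] <- "father"
  role[unique(pm[!is.na(pm)])] <- "mother"
  fa <- which(role == "father"); mo <- which(role == "mother")
  gp <- function(rows, side) {
    r <- match(m$father_id[rows], m$individual_id)
    s <- match(m$mother_id[rows], m$individual_id)
    role[r[!is.na(r)]] <<- paste0("grandfather_", side)
    role[s[!is.na(s)]] <<- paste0("grandmother_", side)
  }
  gp(fa, "paternal"); gp(mo, "maternal")
  list(role = role, generation = gen)
}

#' Import a PLINK-style PED/MAP pair
#'
#' Reconstructs a [FamCohort-class] (roles and generations inferred from
#' the pedigree links; ages are `NA` unless supplied via `phenoFile`) and a
#' [GenotypeTable-class] with minor-allele counts. Variant MAFs are taken
#' from the empirical allele frequency among founders.
#'
#' @param prefix path prefix of the `.ped`/`.map` pair.
#' @param phenoFile optional phenotype TSV from [writePhenotypes()]
#'   supplying age, sex, `Y` and `Z`.
#' @return list with elements `cohort`, `genotypes`, and `phenotypes` (a
#'   data.frame, or `NULL` when no phenotype information is available).
#' @export
readPed <- function(prefix, phenoFile = NULL) {
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE)
  map <- read.table(paste0(prefix, ".map"), header = FALSE)
  nv <- nrow(map)
  m <- data.frame(individual_id = as.integer(ped[[2L]]),
                  family_id = as.integer(ped[[1L]]),
                  father_id = ifelse(ped[[3L]] == 0L, NA_integer_,
                                     as.integer(ped[[3L]])),
                  mother_id = ifelse(ped[[4L]] == 0L, NA_integer_,
                                     as.integer(ped[[4L]])),
                  sex = ifelse(ped[[5L]] == 1L, 0L, 1L),
                  age = NA_real_, stringsAsFactors = FALSE)
  inf <- .inferRoles(m)
  m$role <- inf$role
  m$generation <- inf$generation
  pheno <- NULL
  if (!is.null(phenoFile)) {
    pheno <- readPhenotypes(phenoFile)
    m$age <- pheno$age[match(m$individual_id, pheno$individual_id)]
  } else if (any(ped[[6L]] != -9L)) {
    pheno <- data.frame(individual_id = m$individual_id,
                        family_id = m$family_id,
                        Z = ifelse(ped[[6L]] == -9L, NA_integer_,
                                   as.integer(ped[[6L]]) - 1L))
  }
  mode <- if (max(m$generation) >= 2L) "three_generation" else "nuclear"
  m <- m[, c("individual_id", "family_id", "father_id", "mother_id",
             "role", "sex", "age", "generation")]
  cohort <- new("FamCohort", members = m, mode = mode)
  A <- as.matrix(ped[, 6L + seq_len(2L * nv), drop = FALSE])
  G <- (A[, seq(1L, 2L * nv, 2L), drop = FALSE] == 2L) +
    (A[, seq(2L, 2L * nv, 2L), drop = FALSE] == 2L)
  storage.mode(G) <- "integer"
  dimnames(G) <- list(as.character(m$individual_id),
                      as.character(map[[2L]]))
  fr <- is.na(m$father_id)
  maf <- colMeans(G[fr, , drop = FALSE]) / 2
  geno <- new("GenotypeTable", geno = G,
              variants = data.frame(variant_id = as.character(map[[2L]]),
                                    maf = maf, stringsAsFactors = FALSE))
  list(cohort = cohort, genotypes = geno, phenotypes = pheno)
}

#' Write / read a phenotype and covariate TSV
#'
#' Columns: `individual_id`, `family_id`, `age`, `sex`, `Y`, `Z`, and
#' (when `components = TRUE`) the stored liability components.
#'
#' @param phenos a [PhenotypeSet-class].
#' @param path output file.
#' @param components include the component breakdown (default `TRUE`).
#' @return `writePhenotypes` invisibly returns `path`; `readPhenotypes`
#'   returns a data.frame.
#' @export
writePhenotypes <- function(phenos, path, components = TRUE) {
  d <- phenotypes(phenos)
  if (!components)
    d <- d[, c("individual_id", "family_id", "age", "sex", "Y", "Z")]
  write.table(d, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}

#' Cache a posterior-liability table as TSV
#'
#' The file stores the model parameters (`h2`, `prevalence`, `nmc`, `seed`)
#' in `#`-prefixed header lines followed by the configuration table, so a
#' cached table can be reloaded without re-running the Monte-Carlo
#' integration.
#'
#' @param table a [PosteriorLiabilityTable-class].
#' @param path file path.
#' @return `writePosteriorTable` invisibly returns `path`;
#'   `readPosteriorTable` returns the reconstructed
#'   [PosteriorLiabilityTable-class].
#' @export
writePosteriorTable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# h2=%.17g prevalence=%.17g nmc=%.17g seed=%d",
                     table@h2, table@prevalence, table@nmc,
                     as.integer(table@seed)), con)
  write.table(liabilityTable(table), con, quote = FALSE, sep = "\t",
              row.names = FALSE)
  invisible(path)
}

#' @rdname writePosteriorTable
#' @export
readPosteriorTable <- function(path) {
  hdr <- readLines(path, n = 1L)
  tokens <- strsplit(trimws(sub("^#\\s*", "", hdr)), "\\s+")[[1L]]
  kv <- do.call(rbind, strsplit(tokens, "=", fixed = TRUE))
  vals <- setNames(as.numeric(kv[, 2L]), kv[, 1L])
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  new("PosteriorLiabilityTable", table = tab, h2 = vals[["h2"]],
      prevalence = vals[["prevalence"]], nmc = vals[["nmc"]],
      seed = vals[["seed"]],
      threshold = liabilityThreshold(vals[["prevalence"]]))
}

#' Write a power / type-I table as TSV
#'
#' Numeric cells are rounded to `digits` decimals (three, matching the
#' precision used for reporting).
#'
#' @param tab data.frame from [runPower()], [runType1()] or
#'   [runGrandparentPower()].
#' @param path output file.
#' @param digits decimals for rate columns.
#' @return invisibly, `path`.
#' @export
writePowerTable <- function(tab, path, digits = 3) {
  num <- c("power", "ci_low", "ci_high", "increase_over_ccgwas")
  for (cn in intersect(num, names(tab)))
    tab[[cn]] <- round(tab[[cn]], digits)
  write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
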