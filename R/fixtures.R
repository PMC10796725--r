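## Packaged variety-level tables: GI, biochemical traits and endosperm
## morphometry of 25 Italian genotypes (table3.csv) and morphometry of 11
## further Italian varieties plus 18 IRRI accessions (table4.csv),
## transcribed cell-for-cell with blanks kept as missing values. The
## amylose content of the waxy Castelmochi variety is censored ("<5") in
## the source and is carried as NA plus a censoring flag.

fixturePath <- function(file)
  system.file("extdata", file, package = "endograin", mustWork = TRUE)

checkFixture <- function(df, nrows, checksum, name) {
  numeric <- vapply(df, is.numeric, logical(1))
  got <- round(sum(unlist(df[numeric]), na.rm = TRUE), 2)
  if (nrow(df) != nrows || abs(got - checksum) > 0.01)
    stop("fixture checksum mismatch for ", name,
         " (expected ", nrows, " rows / sum ", checksum,
         ", got ", nrow(df), " / ", got, ")", call. = FALSE)
  df
}

#' Variety-level reference tables
#'
#' `riceTable3()` returns the 25 Italian genotypes with starch-granule
#' morphometry, porosity, biochemical traits and in vivo Glycemic Index;
#' `riceTable4()` the 29 further varieties (11 Italian, 18 IRRI
#' accessions) with morphometry only. Blank cells (varieties whose compact
#' endosperm defeated granule extraction) are NA. `mergedMorphology()`
#' stacks the shared morphometry columns of both tables.
#'
#' @param castelmochiAmylose how to handle the censored "<5" amylose cell:
#'   a numeric imputation value (default 2.5, the censoring midpoint), or
#'   "exclude" to leave it NA.
#' @return data.frame with one row per variety.
#' @examples
#' t3 <- riceTable3()
#' table(classifyGi(t3$gi_mean))
#' @export
riceTable3 <- function(castelmochiAmylose = 2.5) {
  df <- utils::read.csv(fixturePath("table3.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  df$amylose_censored <- df$amylose == "<5" & !is.na(df$amylose)
  df$amylose <- suppressWarnings(as.numeric(df$amylose))
  df <- checkFixture(df, 25, 4425.99, "table3.csv")
  if (is.numeric(castelmochiAmylose))
    df$amylose[df$amylose_censored] <- castelmochiAmylose
  else if (!identical(castelmochiAmylose, "exclude"))
    stop("castelmochiAmylose must be a number or 'exclude'", call. = FALSE)
  df
}

#' @rdname riceTable3
#' @export
riceTable4 <- function() {
  df <- utils::read.csv(fixturePath("table4.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)
  checkFixture(df, 29, 1904.44, "table4.csv")
}

#' @rdname riceTable3
#' @export
mergedMorphology <- function() {
  cols <- c("variety", "area_um2", "area_sd", "eccentricity", "circularity",
            "diameter_um", "porosity_pct", "porosity_sd", "waxy")
  t3 <- riceTable3(); t4 <- riceTable4()
  t3$origin <- "italian"
  out <- rbind(cbind(t3[, cols], source = "table3",
                     origin = t3$origin),
               cbind(t4[, cols], source = "table4", origin = t4$origin))
  rownames(out) <- NULL
  out
}

#' The study's reported correlation pairs
#'
#' Recomputes, from the packaged tables, each correlation the study
#' reports between morphometric, biochemical and glycemic variables, with
#' the subset each one uses: porosity vs mean granule area over all
#' area-bearing varieties; total fat vs GI over the non-waxy Italian
#' genotypes; ashes vs eccentricity (with and without the
#' high-ash outlier Valente); amylose vs GI (censored amylose imputed);
#' circularity vs area (all varieties and Italian only); estimated
#' diameter vs ashes.
#'
#' @param castelmochiAmylose passed to [riceTable3()].
#' @return data.frame: `pair`, `r`, `n`, `subset` description.
#' @export
correlationReport <- function(castelmochiAmylose = 2.5) {
  t3 <- riceTable3(castelmochiAmylose)
  t4 <- riceTable4()
  mm <- mergedMorphology()
  row <- function(pair, res, subset)
    data.frame(pair = pair, r = res$r, n = res$n, subset = subset)
  nonwaxy <- !t3$waxy
  noValente <- !is.na(t3$eccentricity) & t3$variety != "Valente"
  italian <- mm$origin == "italian"
  out <- rbind(
    row("porosity~area",
        pairwisePearson(mm, "area_um2", "porosity_pct"),
        "all varieties with measurable granule area"),
    row("fat~gi",
        pairwisePearson(t3, "fat", "gi_mean", subset = nonwaxy),
        "non-waxy Italian genotypes"),
    row("ashes~eccentricity",
        pairwisePearson(t3, "ashes", "eccentricity"),
        "Italian genotypes with measurable eccentricity"),
    row("ashes~eccentricity_noValente",
        pairwisePearson(t3, "ashes", "eccentricity", subset = noValente),
        "as above, excluding Valente"),
    row("amylose~gi",
        pairwisePearson(t3, "amylose", "gi_mean"),
        "all 25 Italian genotypes, censored amylose imputed"),
    row("circularity~area",
        pairwisePearson(mm, "circularity", "area_um2"),
        "all varieties with both printed"),
    row("circularity~area_italian",
        pairwisePearson(mm, "circularity", "area_um2", subset = italian),
        "Italian varieties only"),
    row("diameter~ashes",
        pairwisePearson(t3, "diameter_um", "ashes"),
        "Italian genotypes with printed diameter"))
  rownames(out) <- NULL
  out
}

#' Reproduce the published variety-table derivations
#'
#' Re-derives from the packaged tables everything in them that is a
#' computation rather than a measurement: the equivalent circular diameter
#' of every variety with both a printed mean area and a printed diameter
#' (matched to +/- 0.01 um), the low/medium/high Glycemic Index
#' classification counts, the headline GI range, and the reported
#' correlations (matched to +/- 0.02, the printed-cell rounding
#' tolerance). Aborts if a fixture fails its checksum.
#'
#' @return data.frame with one row per check: `check`, `value`, `target`,
#'   `pass`.
#' @examples
#' reproduceTables()
#' @export
reproduceTables <- function() {
  t3 <- riceTable3()
  t4 <- riceTable4()
  checks <- list()
  add <- function(check, value, target, pass)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, value = value, target = target, pass = pass)

  for (tb in list(c(name = "table3"), c(name = "table4"))) {
    df <- if (tb["name"] == "table3") t3 else t4
    both <- !is.na(df$area_um2) & !is.na(df$diameter_um)
    d <- roundHalfUp(equivalentDiameter(df$area_um2[both]), 2)
    ok <- abs(d - df$diameter_um[both]) <= 0.01 + 1e-9
    add(paste0("diameters_", tb["name"]), sum(ok), sum(both), all(ok))
  }

  counts <- table(factor(classifyGi(t3$gi_mean),
                         levels = c("low", "medium", "high")))
  add("gi_class_low", counts[["low"]], 5, counts[["low"]] == 5)
  add("gi_class_medium", counts[["medium"]], 10, counts[["medium"]] == 10)
  add("gi_class_high", counts[["high"]], 10, counts[["high"]] == 10)
  add("gi_max_rounded", round(max(t3$gi_mean)), 92,
      round(max(t3$gi_mean)) == 92)
  add("gi_min_rounded", round(min(t3$gi_mean)), 49,
      round(min(t3$gi_mean)) == 49)

  rep <- correlationReport()
  targets <- c("porosity~area" = -0.5822, "fat~gi" = -0.3265,
               "ashes~eccentricity" = 0.5181,
               "ashes~eccentricity_noValente" = 0.5216)
  for (p in names(targets)) {
    r <- rep$r[rep$pair == p]
    add(paste0("cor_", p), r, targets[[p]],
        is.finite(r) && abs(r - targets[[p]]) <= 0.02)
  }
  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
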