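#' Summarize bundle-sheath ultrastructure measurements
#'
#' Per-cell planar measurements are reduced to per-plant means, then averaged
#' across plants per species, with significance letters from one-way ANOVA
#' followed by Tukey's HSD (alpha = 0.05) on the per-plant means. Metrics:
#' cell area; percent of the cell covered by each organelle kind
#' (sum of organelle areas / cell area * 100); organelle counts per cell
#' (median and range across all cells of the species); and mean area per
#' organelle. Letters are only computed when every species has at least two
#' plants.
#'
#' @param cells `data.frame` with columns `species`, `plant`, `cell`,
#'   `cell_area` (um2), one row per measured cell.
#' @param organelles `data.frame` with columns `plant`, `cell`, `kind`
#'   (`"chloroplast"` or `"mitochondrion"`), `area` (um2), one row per
#'   organelle; cells with no organelles of a kind simply have no rows.
#' @param alpha Significance level for the Tukey letters.
#' @return List: `species` (wide per-species summary with means, sds, count
#'   medians/ranges), `per_plant` (the per-plant metric table) and `letters`
#'   (`data.frame` metric x species of group letters, or `NULL` when any
#'   species has a single plant).
#' @export
ultrastructureSummary <- function(cells, organelles, alpha = 0.05) {
  stopifnot(all(c("species", "plant", "cell", "cell_area") %in% names(cells)),
            all(c("plant", "cell", "kind", "area") %in% names(organelles)))
  kinds <- c("chloroplast", "mitochondrion")
  if (!all(organelles$kind %in% kinds)) {
    stop("organelle kind must be one of: ", paste(kinds, collapse = ", "))
  }
  key <- function(p, cl) paste(p, cl, sep = "\r")
  cells$.k <- key(cells$plant, cells$cell)
  organelles$.k <- key(organelles$plant, organelles$cell)
  orphan <- setdiff(organelles$.k, cells$.k)
  if (length(orphan)) stop("organelle rows reference unmeasured cells")

  # per-cell derived values
  for (kd in kinds) {
    sub <- organelles[organelles$kind == kd, , drop = FALSE]
    tot <- tapply(sub$area, sub$.k, sum)
    cnt <- tapply(sub$area, sub$.k, length)
    cells[[paste0("area_", kd)]] <- unname(ifelse(is.na(tot[cells$.k]), 0, tot[cells$.k]))
    cells[[paste0("n_", kd)]] <- unname(ifelse(is.na(cnt[cells$.k]), 0, cnt[cells$.k]))
    cells[[paste0("pct_", kd)]] <- 100 * cells[[paste0("area_", kd)]] / cells$cell_area
    if (any(cells[[paste0("pct_", kd)]] > 100)) {
      stop("organelle areas exceed cell area for kind ", kd)
    }
  }

  # per-plant means for each metric
  metrics <- c("cell_area", paste0("pct_", kinds), paste0("n_", kinds))
  pp <- do.call(rbind, lapply(split(cells, list(cells$species, cells$plant),
                                    drop = TRUE), function(d) {
    row <- data.frame(species = d$species[1], plant = d$plant[1],
                      stringsAsFactors = FALSE)
    for (m in metrics) row[[m]] <- mean(d[[m]])
    for (kd in kinds) {
      sub <- organelles[organelles$kind == kd &
                        organelles$.k %in% d$.k, , drop = FALSE]
      row[[paste0("mean_area_", kd)]] <- if (nrow(sub)) mean(sub$area) else 0
    }
    row
  }))
  rownames(pp) <- NULL
  all_metrics <- c(metrics, paste0("mean_area_", kinds))

  # species-level summary
  sp_split <- split(pp, pp$species)
  summ <- do.call(rbind, lapply(sp_split, function(d) {
    row <- data.frame(species = d$species[1], n_plants = nrow(d),
                      stringsAsFactors = FALSE)
    for (m in all_metrics) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      row[[paste0(m, "_sd")]] <- if (nrow(d) > 1) sd(d[[m]]) else NA_real_
    }
    cl <- cells[cells$species == d$species[1], , drop = FALSE]
    for (kd in kinds) {
      n <- cl[[paste0("n_", kd)]]
      row[[paste0("n_", kd, "_median")]] <- stats::median(n)
      row[[paste0("n_", kd, "_min")]] <- min(n)
      row[[paste0("n_", kd, "_max")]] <- max(n)
    }
    row
  }))
  rownames(summ) <- NULL

  letters <- NULL
  if (all(summ$n_plants >= 2) && length(sp_split) >= 2) {
    letters <- do.call(rbind, lapply(all_metrics, function(m) {
      d <- data.frame(species = factor(pp$species), value = pp[[m]])
      lt <- tryCatch({
        fit <- aov(value ~ species, data = d)
        cld <- multcomp::cld(multcomp::glht(fit,
          linfct = multcomp::mcp(species = "Tukey")), level = 1 - alpha)
        cld$mcletters$Letters
      }, error = function(e) {
        stats::setNames(rep(NA_character_, nlevels(d$species)),
                        levels(d$species))
      })
      out <- data.frame(metric = m, t(as.data.frame(lt)),
                        stringsAsFactors = FALSE, check.names = FALSE)
      rownames(out) <- NULL
      out
    }))
  }
  list(species = summ, per_plant = pp, letters = letters)
}
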