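#' @include AllClasses.R
NULL

#' Build region instances from verified contacts
#'
#' Collapses verified gray-matter contacts to one instance per distinct
#' (patient, hemisphere, region).  An instance is SOZ-positive iff any of
#' its contacts carries the SEEG seizure-onset flag (any-contact rule).
#' The lobe of each instance comes from the lookup table; a verified
#' contact whose region is missing from the lookup is an error.
#'
#' @param contact_table the [ContactTable-class] carrying soz_flag per
#'   contact.
#' @param assignment_report data.frame from
#'   [filterGrayMatterContacts()]`$report` (contact_id, region,
#'   hemisphere, verified).
#' @param lobe_table data.frame(hemisphere, region, lobe), e.g.
#'   [destrieuxLobeTable()] or a [Parcellation-class] lobe lookup expanded
#'   per hemisphere.
#' @param patient_id identifier stamped on the instances.
#' @return data.frame with columns patient, hemisphere, region, lobe,
#'   is_soz — one row per region instance.
#' @export
buildRegionInstances <- function(contact_table, assignment_report,
                                 lobe_table, patient_id = "p1") {
  stopifnot(is(contact_table, "ContactTable"),
            all(c("contact_id", "region", "hemisphere", "verified") %in%
                  names(assignment_report)),
            all(c("hemisphere", "region", "lobe") %in% names(lobe_table)))
  df <- merge(contact_table@contacts[, c("contact_id", "soz_flag")],
              assignment_report, by = "contact_id")
  df <- df[df$verified, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(patient = character(), hemisphere = character(),
                      region = character(), lobe = character(),
                      is_soz = logical()))
  key <- paste(df$hemisphere, df$region, sep = "\r")
  lobeKey <- paste(lobe_table$hemisphere, lobe_table$region, sep = "\r")
  miss <- setdiff(unique(key), lobeKey)
  if (length(miss))
    stop("contact(s) reference region(s) unknown to the lobe table: ",
         paste(gsub("\r", " ", miss), collapse = ", "))
  soz <- tapply(df$soz_flag, key, any)
  keys <- sort(names(soz))
  out <- data.frame(
    patient = patient_id,
    hemisphere = sub("\r.*$", "", keys),
    region = sub("^.*\r", "", keys),
    lobe = lobe_table$lobe[match(keys, lobeKey)],
    is_soz = as.logical(soz[keys]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cross-classify region instances against hypometabolic regions
#'
#' Marks each instance hypometabolic iff its (hemisphere, region) appears
#' in the Z-map's hypometabolic set (per patient when the set carries a
#' patient column), then tallies the 2x2 confusion counts:
#' TP = SOZ & hypometabolic, FP = non-SOZ & hypometabolic,
#' FN = SOZ & non-hypometabolic, TN = non-SOZ & non-hypometabolic.
#'
#' @param instances data.frame from [buildRegionInstances()] (possibly
#'   concatenated over patients).
#' @param hypometabolic_regions data.frame(hemisphere, region), optionally
#'   with a patient column for per-patient matching, or a
#'   [HypometabolicSet-class].
#' @return list with `counts` (named vector TP, FP, FN, TN) and
#'   `instances` (input augmented with is_hypometabolic).
#' @export
crossClassify <- function(instances, hypometabolic_regions) {
  if (is(hypometabolic_regions, "HypometabolicSet"))
    hypometabolic_regions <- hypometabolic_regions@regions
  stopifnot(nrow(instances) > 0)
  perPatient <- "patient" %in% names(hypometabolic_regions) &&
    nrow(hypometabolic_regions) > 0
  ikey <- if (perPatient)
    paste(instances$patient, instances$hemisphere, instances$region)
  else paste(instances$hemisphere, instances$region)
  hkey <- if (perPatient)
    paste(hypometabolic_regions$patient, hypometabolic_regions$hemisphere,
          hypometabolic_regions$region)
  else if (nrow(hypometabolic_regions))
    paste(hypometabolic_regions$hemisphere, hypometabolic_regions$region)
  else character()
  hypo <- ikey %in% hkey
  soz <- instances$is_soz
  counts <- c(TP = sum(soz & hypo), FP = sum(!soz & hypo),
              FN = sum(soz & !hypo), TN = sum(!soz & !hypo))
  instances$is_hypometabolic <- hypo
  list(counts = counts, instances = instances)
}

#' Six concordance metrics from 2x2 confusion counts
#'
#' TPR = TP/(TP+FN), TNR = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), ACC = (TP+TN)/N and Cohen's kappa
#' `(p_o - p_e)/(1 - p_e)` with `p_o = ACC` and the chance agreement
#' `p_e = ((TP+FN)(TP+FP) + (FP+TN)(FN+TN)) / N^2`.  Metrics with a zero
#' denominator (and kappa when `p_e = 1`) are returned as NA — flagged
#' undefined, never silently zeroed.
#'
#' @param counts named numeric vector with elements TP, FP, FN, TN
#'   (N = sum must be > 0).
#' @param stratum label for the Category column.
#' @return one-row data.frame: Category, N, TP, FP, FN, TN, TPR, TNR,
#'   PPV, NPV, ACC, Kappa.
#' @export
computeMetrics <- function(counts, stratum = "Total") {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  fn <- counts[["FN"]]; tn <- counts[["TN"]]
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  n <- tp + fp + fn + tn
  if (n == 0) stop("confusion counts sum to zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) NA_real_ else (acc - pe) / (1 - pe)
  data.frame(Category = stratum, N = n, TP = tp, FP = fp, FN = fn, TN = tn,
             TPR = ratio(tp, tp + fn), TNR = ratio(tn, tn + fp),
             PPV = ratio(tp, tp + fp), NPV = ratio(tn, tn + fn),
             ACC = acc, Kappa = kappa, stringsAsFactors = FALSE)
}

#' Stratified concordance report (Total, per lobe, per hemisphere)
#'
#' Computes the six metrics for the whole instance set and for each lobe
#' and hemisphere stratum.  Sub-strata with fewer instances than `floor`
#' are flagged not-reported (metrics NA, reported = FALSE) rather than
#' printed as unstable numbers; the Total row is always reported.
#'
#' @param instances data.frame of region instances.
#' @param hypometabolic_regions see [crossClassify()].
#' @param floor minimum instance count for numeric sub-stratum reporting
#'   (default 30).
#' @return A [ConcordanceResult-class]; its metrics table has one row per
#'   stratum with columns Category, N, TP, FP, FN, TN, the six metrics and
#'   `reported`.
#' @export
stratifyAndReport <- function(instances, hypometabolic_regions,
                              floor = 30) {
  cc <- crossClassify(instances, hypometabolic_regions)
  inst <- cc$instances
  strata <- list(Total = rep(TRUE, nrow(inst)))
  for (lb in c("frontal", "parietal", "temporal", "occipital", "insular"))
    strata[[paste(tools::toTitleCase(lb), "lobe")]] <- inst$lobe == lb
  strata[["Left hemisphere"]] <- inst$hemisphere == "lh"
  strata[["Right hemisphere"]] <- inst$hemisphere == "rh"
  rows <- lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    if (!any(sel)) {
      row <- data.frame(Category = nm, N = 0L, TP = 0, FP = 0, FN = 0,
                        TN = 0, TPR = NA_real_, TNR = NA_real_,
                        PPV = NA_real_, NPV = NA_real_, ACC = NA_real_,
                        Kappa = NA_real_, stringsAsFactors = FALSE)
      row$reported <- FALSE
      return(row)
    }
    sub <- inst[sel, , drop = FALSE]
    counts <- c(TP = sum(sub$is_soz & sub$is_hypometabolic),
                FP = sum(!sub$is_soz & sub$is_hypometabolic),
                FN = sum(sub$is_soz & !sub$is_hypometabolic),
                TN = sum(!sub$is_soz & !sub$is_hypometabolic))
    row <- computeMetrics(counts, stratum = nm)
    row$reported <- nm == "Total" || sum(sel) >= floor
    if (!row$reported)
      row[c("TPR", "TNR", "PPV", "NPV", "ACC", "Kappa")] <- NA_real_
    row
  })
  new("ConcordanceResult",
      metrics = do.call(rbind, c(rows, list(make.row.names = FALSE))),
      floor = floor)
}
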