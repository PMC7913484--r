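#' Pollen frequency class
#'
#' Melissopalynological convention for the relative frequency of a pollen
#' type in a honey sediment: predominant (> 45%), secondary (15-45%),
#' important minor (3 to < 15%), minor (< 3%). Boundaries are closed on the
#' lower side.
#'
#' @param pct percentage(s) in [0, 100].
#' @return factor with levels `predominant`, `secondary`,
#'   `important_minor`, `minor`.
#' @export
frequency_class <- function(pct) {
  pct <- as.numeric(pct)
  if (any(pct < 0 | pct > 100))
    stop("pollen percentage out of [0, 100]: ", pct[pct < 0 | pct > 100][1])
  out <- ifelse(pct > 45, "predominant",
         ifelse(pct >= 15, "secondary",
         ifelse(pct >= 3, "important_minor", "minor")))
  factor(out, levels = c("predominant", "secondary", "important_minor", "minor"))
}

#' Default honey-typing rules
#'
#' One rule per unifloral class: a main pollen taxon and a minimum
#' percentage. Heather honeys carry under-represented *Erica* pollen, so
#' their threshold (35%) is far below the predominance cutoff and the rule
#' fires first; chestnut and eucalyptus pollen are over-represented, hence
#' the high 70% cutoffs. Honeydew honey has no pollen signature of its own:
#' the stand-in rule requires predominant *Castanea* below the chestnut
#' cutoff together with the high electrical conductivity (>= 0.8 mS/cm)
#' characteristic of honeydew. Anything unmatched is multifloral.
#'
#' @return object of class `typing_rules`: list with `unifloral` (data frame
#'   of honey_type, taxon, min_pct, in precedence order), `honeydew` (list
#'   with `taxon`, `min_pct`, `min_ec_ms_cm`) and `default` class name.
#' @export
default_typing_rules <- function() {
  structure(list(
    unifloral = data.frame(
      honey_type = c("heather", "eucalyptus", "blackberry", "chestnut"),
      taxon = c("Erica", "Eucalyptus", "Rubus", "Castanea"),
      min_pct = c(35, 70, 45, 70),
      stringsAsFactors = FALSE
    ),
    honeydew = list(taxon = "Castanea", min_pct = 45, min_ec_ms_cm = 0.8),
    default = "multifloral"
  ), class = "typing_rules")
}

#' Assign a honey type from a pollen profile
#'
#' Rules are tried in precedence order (under-represented taxa first); the
#' first match wins and the trace records the rule and triggering
#' percentage. The honeydew rule needs an electrical conductivity; without
#' one it cannot fire. Unmatched profiles default to multifloral.
#'
#' @param profile named numeric vector (or one-row data frame) of pollen
#'   percentages; should sum to ~100.
#' @param ec_ms_cm optional electrical conductivity in mS/cm.
#' @param rules a `typing_rules` object (default [default_typing_rules()]).
#' @return list with `honey_type` and `trace` (human-readable matched rule).
#' @export
assign_honey_type <- function(profile, ec_ms_cm = NULL,
                              rules = default_typing_rules()) {
  if (is.data.frame(profile)) profile <- unlist(profile[1, , drop = TRUE])
  profile <- profile[!is.na(profile)]
  if (any(profile < 0)) stop("negative pollen percentage")
  tot <- sum(profile)
  if (abs(tot - 100) > 0.5)
    warning("pollen percentages sum to ", format(tot), ", not 100")
  get_pct <- function(taxon) {
    if (!taxon %in% names(profile)) {
      warning("rule taxon '", taxon, "' absent from profile; rule skipped")
      return(NA_real_)
    }
    as.numeric(profile[taxon])
  }
  for (i in seq_len(nrow(rules$unifloral))) {
    r <- rules$unifloral[i, ]
    pct <- get_pct(r$taxon)
    if (!is.na(pct) && pct >= r$min_pct) {
      return(list(honey_type = r$honey_type,
                  trace = sprintf("%s: %s %.1f%% >= %.0f%%",
                                  r$honey_type, r$taxon, pct, r$min_pct)))
    }
  }
  hd <- rules$honeydew
  if (!is.null(hd) && !is.null(ec_ms_cm) && !is.na(ec_ms_cm)) {
    pct <- get_pct(hd$taxon)
    if (!is.na(pct) && pct >= hd$min_pct && ec_ms_cm >= hd$min_ec_ms_cm) {
      return(list(honey_type = "honeydew",
                  trace = sprintf(
                    "honeydew: %s %.1f%% >= %.0f%% and EC %.2f mS/cm >= %.2f",
                    hd$taxon, pct, hd$min_pct, ec_ms_cm, hd$min_ec_ms_cm)))
    }
  }
  list(honey_type = rules$default,
       trace = paste0(rules$default, ": no unifloral rule matched"))
}

#' Type every sample in a pollen table
#'
#' @param pollen data frame, samples x pollen-type percentages, with an
#'   optional `sample_id` column.
#' @param ec_ms_cm optional numeric vector of conductivities (mS/cm) aligned
#'   with the rows.
#' @param rules a `typing_rules` object.
#' @return data frame with `sample_id`, `honey_type`, `trace`.
#' @export
assign_honey_types <- function(pollen, ec_ms_cm = NULL,
                               rules = default_typing_rules()) {
  pollen <- as.data.frame(pollen)
  ids <- if ("sample_id" %in% names(pollen)) {
    v <- as.character(pollen$sample_id)
    pollen$sample_id <- NULL
    v
  } else rownames(pollen)
  out <- vector("list", nrow(pollen))
  for (i in seq_len(nrow(pollen))) {
    ec <- if (is.null(ec_ms_cm)) NULL else ec_ms_cm[i]
    out[[i]] <- assign_honey_type(unlist(pollen[i, , drop = TRUE]), ec, rules)
  }
  data.frame(sample_id = ids,
             honey_type = vapply(out, `[[`, character(1), "honey_type"),
             trace = vapply(out, `[[`, character(1), "trace"),
             stringsAsFactors = FALSE)
}
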