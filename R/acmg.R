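#' @include AllClasses.R stats-core.R
NULL

.ACMG_IDS <- c("PVS1",
               paste0("PS", 1:4), paste0("PM", 1:6), paste0("PP", 1:5),
               "BA1", paste0("BS", 1:4), paste0("BP", 1:7))

.NATIVE_STRENGTH <- c(
  PVS1 = "very_strong",
  stats::setNames(rep("strong", 4), paste0("PS", 1:4)),
  stats::setNames(rep("moderate", 6), paste0("PM", 1:6)),
  stats::setNames(rep("supporting", 5), paste0("PP", 1:5)),
  BA1 = "stand_alone",
  stats::setNames(rep("strong", 4), paste0("BS", 1:4)),
  stats::setNames(rep("supporting", 7), paste0("BP", 1:7)))

.MODIFIERS <- c(S = "strong", M = "moderate", P = "supporting")

#' Parse an ACMG evidence token
#'
#' Tokens are canonical criterion names, optionally re-weighted with a strength
#' modifier suffix: \code{_S} (strong), \code{_M} (moderate), \code{_P}
#' (supporting). Without a modifier the criterion keeps its native strength
#' (e.g. PVS1 is very strong, PS2 strong, PM2 moderate, PP3 supporting).
#'
#' @param token character, e.g. \code{"PS2_M"} or \code{"PVS1"}.
#' @return list with \code{id}, \code{applied_strength}, \code{benign}
#'   (TRUE for BA/BS/BP criteria).
#' @examples
#' parseEvidence("PM2_P")  # PM2 applied at supporting strength
#' @export
parseEvidence <- function(token) {
  token <- trimws(token)
  parts <- strsplit(token, "_", fixed = TRUE)[[1]]
  id <- parts[1]
  if (!id %in% .ACMG_IDS)
    stop("unknown ACMG criterion in token '", token, "'")
  strength <- unname(.NATIVE_STRENGTH[id])
  if (length(parts) > 1L) {
    if (length(parts) > 2L || !parts[2] %in% names(.MODIFIERS))
      stop("unknown strength modifier in token '", token, "'")
    strength <- unname(.MODIFIERS[parts[2]])
  }
  list(id = id, applied_strength = strength,
       benign = grepl("^B", id))
}

#' Parse a combined evidence string
#'
#' @param string evidence codes joined by \code{+}, e.g.
#'   \code{"PVS1_S+PS2_M+PM2_P"}.
#' @return list of parsed evidence codes (see \code{\link{parseEvidence}}).
#' @export
parseEvidenceSet <- function(string) {
  tokens <- strsplit(string, "+", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(trimws(tokens))]
  lapply(tokens, parseEvidence)
}

# counts of applied strengths on each side of the evidence
.strength_counts <- function(codes) {
  tab <- function(side) {
    s <- vapply(codes[vapply(codes, `[[`, logical(1), "benign") == side],
                `[[`, character(1), "applied_strength")
    c(stand_alone = sum(s == "stand_alone"),
      very_strong = sum(s == "very_strong"),
      strong = sum(s == "strong"),
      moderate = sum(s == "moderate"),
      supporting = sum(s == "supporting"))
  }
  list(path = tab(FALSE), benign = tab(TRUE))
}

.pathogenic_rule <- function(cn) {
  vs <- cn["very_strong"]; s <- cn["strong"]; m <- cn["moderate"]; p <- cn["supporting"]
  if (vs >= 2) return("P: >=2 very strong")
  if (vs >= 1 && (s >= 1 || m >= 2 || (m >= 1 && p >= 1) || p >= 2))
    return("P: 1 very strong + corroboration")
  if (s >= 2) return("P: >=2 strong")
  if (s >= 1 && (m >= 3 || (m >= 2 && p >= 2) || (m >= 1 && p >= 4)))
    return("P: 1 strong + moderate/supporting")
  NULL
}

.likely_pathogenic_rule <- function(cn) {
  vs <- cn["very_strong"]; s <- cn["strong"]; m <- cn["moderate"]; p <- cn["supporting"]
  if (vs >= 1 && m >= 1) return("LP: 1 very strong + 1 moderate")
  if (s >= 1 && m >= 1) return("LP: 1 strong + 1-2 moderate")
  if (s >= 1 && p >= 2) return("LP: 1 strong + >=2 supporting")
  if (m >= 3) return("LP: >=3 moderate")
  if (m >= 2 && p >= 2) return("LP: 2 moderate + >=2 supporting")
  if (m >= 1 && p >= 4) return("LP: 1 moderate + >=4 supporting")
  NULL
}

.benign_rule <- function(cn) {
  if (cn["stand_alone"] >= 1) return("B: stand-alone (BA1)")
  if (cn["strong"] >= 2) return("B: >=2 benign strong")
  NULL
}

.likely_benign_rule <- function(cn) {
  if (cn["strong"] >= 1 && cn["supporting"] >= 1)
    return("LB: 1 benign strong + 1 benign supporting")
  if (cn["supporting"] >= 2) return("LB: >=2 benign supporting")
  NULL
}

#' Combine ACMG evidence into a five-tier classification
#'
#' Applies the ACMG/AMP combining rules to a set of evidence codes, counting
#' each code at its \emph{applied} strength (a PVS1_S counts as one strong, a
#' PS2_M as one moderate). When both a pathogenic-side and a benign-side rule
#' are satisfied the evidence is contradictory and the verdict is uncertain
#' significance, as it is when no rule fires.
#'
#' @param evidence a character string (\code{"PVS1+PM2_P+PP5"}), a character
#'   vector of tokens, or a list of parsed codes.
#' @return list with \code{tier} (one of \code{pathogenic},
#'   \code{likely_pathogenic}, \code{uncertain_significance},
#'   \code{likely_benign}, \code{benign}) and \code{fired_rule} (NA for
#'   uncertain significance).
#' @examples
#' classifyEvidence("PVS1+PM2_P+PP5")$tier        # pathogenic
#' classifyEvidence("PVS1_S+PS2_M+PM2_P")$tier    # likely_pathogenic
#' classifyEvidence("PS2_M+PM2_P")$tier           # uncertain_significance
#' @export
classifyEvidence <- function(evidence) {
  codes <- if (is.character(evidence) && length(evidence) == 1L)
    parseEvidenceSet(evidence)
  else if (is.character(evidence)) lapply(evidence, parseEvidence)
  else evidence
  cn <- .strength_counts(codes)
  path_rule <- .pathogenic_rule(cn$path)
  lp_rule <- .likely_pathogenic_rule(cn$path)
  ben_rule <- .benign_rule(cn$benign)
  lb_rule <- .likely_benign_rule(cn$benign)
  path_fired <- if (!is.null(path_rule)) path_rule else lp_rule
  ben_fired <- if (!is.null(ben_rule)) ben_rule else lb_rule
  if (!is.null(path_fired) && !is.null(ben_fired))
    return(list(tier = "uncertain_significance", fired_rule = NA_character_))
  if (!is.null(path_rule)) return(list(tier = "pathogenic", fired_rule = path_rule))
  if (!is.null(lp_rule)) return(list(tier = "likely_pathogenic", fired_rule = lp_rule))
  if (!is.null(ben_rule)) return(list(tier = "benign", fired_rule = ben_rule))
  if (!is.null(lb_rule)) return(list(tier = "likely_benign", fired_rule = lb_rule))
  list(tier = "uncertain_significance", fired_rule = NA_character_)
}

#' Candidate-variant filter parameters
#'
#' @param func_classes admitted functional classes.
#' @param maf_max maximum tolerated population frequency (default 0.0005,
#'   i.e. 0.05 percent).
#' @param maf_rule \code{"max"} requires the maximum frequency over all
#'   databases to pass (strictest reading, default); \code{"any"} requires
#'   only one database below the cutoff.
#' @param require_segregation,require_phenotype_match whether the caller-
#'   supplied co-segregation / phenotype-correlation judgments are required.
#' @return list of parameters for \code{\link{candidateFilter}}.
#' @export
candidateFilterParams <- function(func_classes = c("missense", "frameshift",
                                                   "stop_gain", "stop_loss",
                                                   "start_loss", "splice"),
                                  maf_max = 0.0005,
                                  maf_rule = c("max", "any"),
                                  require_segregation = TRUE,
                                  require_phenotype_match = TRUE) {
  stopifnot(maf_max > 0, maf_max < 1)
  list(func_classes = func_classes, maf_max = maf_max,
       maf_rule = match.arg(maf_rule),
       require_segregation = require_segregation,
       require_phenotype_match = require_phenotype_match)
}

#' Candidate-variant filter for CP-gene analysis
#'
#' A variant is a candidate when its functional class is admitted, it is rare
#' in every population database (absent frequencies count as 0, never as a
#' failure), its gene is on the curated CP-gene list, and the caller-supplied
#' co-segregation and phenotype-correlation judgments hold. Clinical
#' judgments are inputs, not computed.
#'
#' @param records data.frame of variant records (see
#'   \code{\link{TrioVariantTable}}).
#' @param params see \code{\link{candidateFilterParams}}.
#' @param cp_genes character vector of CP-associated gene symbols.
#' @param segregation_ok,phenotype_ok logical vectors (recycled) of clinical
#'   judgments per record.
#' @return data.frame with columns \code{pass} and \code{reasons}
#'   (semicolon-joined failed criteria; empty iff pass).
#' @export
candidateFilter <- function(records, params = candidateFilterParams(),
                            cp_genes, segregation_ok = TRUE,
                            phenotype_ok = TRUE) {
  n <- nrow(records)
  segregation_ok <- rep_len(segregation_ok, n)
  phenotype_ok <- rep_len(phenotype_ok, n)
  maf <- as.matrix(records[, paste0("maf_", MAF_DATABASES), drop = FALSE])
  maf[is.na(maf)] <- 0
  maf_pass <- if (params$maf_rule == "max")
    apply(maf, 1L, max) < params$maf_max
  else apply(maf, 1L, min) < params$maf_max
  reasons <- vector("list", n)
  for (i in seq_len(n)) {
    r <- character(0)
    if (is.na(records$func_class[i]) ||
        !records$func_class[i] %in% params$func_classes)
      r <- c(r, "functional class")
    if (!maf_pass[i]) r <- c(r, "population frequency")
    if (is.na(records$gene[i]) || !records$gene[i] %in% cp_genes)
      r <- c(r, "not a CP gene")
    if (params$require_segregation && !isTRUE(segregation_ok[i]))
      r <- c(r, "segregation")
    if (params$require_phenotype_match && !isTRUE(phenotype_ok[i]))
      r <- c(r, "phenotype match")
    reasons[[i]] <- r
  }
  data.frame(pass = lengths(reasons) == 0L,
             reasons = vapply(reasons, paste, character(1), collapse = "; "),
             stringsAsFactors = FALSE)
}

#' Classify a cohort evidence table
#'
#' Takes rows of (sample, gene, evidence string), classifies each variant and
#' summarises carriers per tier group.
#'
#' @param table data.frame with columns \code{sample}, \code{gene},
#'   \code{evidence} (and optionally others, carried through).
#' @return list with \code{classified} (input plus \code{tier} and
#'   \code{fired_rule} columns), \code{n_probands_plp} (distinct samples with
#'   at least one P or LP variant), \code{n_probands_vus_only} (distinct
#'   samples whose variants are all VUS).
#' @export
classifyCohort <- function(table) {
  if (nrow(table) == 0L)
    return(list(classified = cbind(table, tier = character(0),
                                   fired_rule = character(0)),
                n_probands_plp = 0L, n_probands_vus_only = 0L))
  cls <- lapply(table$evidence, classifyEvidence)
  table$tier <- vapply(cls, `[[`, character(1), "tier")
  table$fired_rule <- vapply(cls, function(x)
    if (is.na(x$fired_rule)) NA_character_ else x$fired_rule, character(1))
  plp <- unique(table$sample[table$tier %in% c("pathogenic", "likely_pathogenic")])
  vus <- unique(table$sample[table$tier == "uncertain_significance"])
  list(classified = table,
       n_probands_plp = length(plp),
       n_probands_vus_only = length(setdiff(vus, plp)))
}
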