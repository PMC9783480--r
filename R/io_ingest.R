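#' @title Reading and validating treatment-level development-time tables
#' @name io_ingest
#' @description
#' Primary data arrive as one row per (dataset, treatment): a treatment value
#' (rearing temperature in degrees C, or a diet label), the male and female
#' mean development times (days) and their standard errors. Rows are grouped
#' into primary datasets, validated against the corpus invariants (positive
#' means, non-negative SEs, distinct treatment values, at least two
#' treatments) and classified as quantitative (all SEs present, eligible for
#' the weighted meta-analysis) or qualitative-only.
NULL

#' Default column map for primary tables
#'
#' @return Named character vector mapping internal field names to the
#'   default CSV header names.
#' @export
default_dialect <- function() {
  c(dataset_id = "dataset_id", study_id = "study_id", species = "species",
    order_name = "order_name", trait = "trait", factor = "factor",
    treatment_value = "treatment_value",
    male_mean = "male_mean_dt", male_se = "male_se",
    female_mean = "female_mean_dt", female_se = "female_se")
}

#' Construct a primary dataset
#'
#' A primary dataset is an ordered set of treatment records from one
#' experiment on one species and one development-time trait.
#'
#' @param dataset_id,study_id,species,order_name Identifier strings.
#' @param trait `"total"` or `"larval"`.
#' @param factor `"temperature"` or `"diet"`.
#' @param records Data frame with columns `treatment_value`, `male_mean`,
#'   `male_se`, `female_mean`, `female_se`; one row per treatment, order
#'   preserved. SEs may be `NA` (missing), never silently zero.
#' @return An object of class `primary_dataset`.
#' @export
primary_dataset <- function(dataset_id, study_id, species, order_name = NA_character_,
                            trait = c("total", "larval"),
                            factor = c("temperature", "diet"),
                            records) {
  trait <- match.arg(trait)
  factor <- match.arg(factor)
  stopifnot(is.data.frame(records))
  need <- c("treatment_value", "male_mean", "male_se", "female_mean", "female_se")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (nrow(records) < 2L)
    stop("primary dataset '", dataset_id, "' needs at least 2 treatments")
  if (anyDuplicated(records$treatment_value))
    stop("duplicate treatment values in dataset '", dataset_id, "'")
  if (any(!is.finite(records$male_mean)) || any(!is.finite(records$female_mean)) ||
      any(records$male_mean <= 0) || any(records$female_mean <= 0))
    stop("development-time means must be strictly positive in dataset '", dataset_id, "'")
  if (any(records$male_se < 0, na.rm = TRUE) || any(records$female_se < 0, na.rm = TRUE))
    stop("standard errors must be non-negative in dataset '", dataset_id, "'")
  has_se <- !anyNA(records$male_se) && !anyNA(records$female_se)
  structure(
    list(dataset_id = as.character(dataset_id), study_id = as.character(study_id),
         species = as.character(species), order_name = as.character(order_name),
         trait = trait, factor = factor,
         records = records[, need], has_se = has_se, k = nrow(records)),
    class = "primary_dataset")
}

#' @export
print.primary_dataset <- function(x, ...) {
  cat(sprintf("<primary_dataset %s> %s (%s), %s %s, k = %d treatments, SEs %s\n",
              x$dataset_id, x$species, x$order_name, x$factor, x$trait, x$k,
              if (x$has_se) "complete" else "incomplete"))
  invisible(x)
}

#' Read a treatment-level primary table
#'
#' Reads a CSV with one row per (dataset, treatment), groups rows into
#' [primary_dataset] objects preserving row order within each dataset, and
#' collects invalid rows / datasets in a reject report. Every input row lands
#' either in a returned dataset or in the reject report (row conservation).
#'
#' @param path CSV file path (UTF-8, header row).
#' @param dialect Named character vector mapping internal field names to the
#'   file's column names; see [default_dialect()]. Fields `order_name`,
#'   `male_se`, `female_se` are optional in the file.
#' @param dec Decimal separator, `"."` (default) or `","`.
#' @return A list with elements `datasets` (list of `primary_dataset`),
#'   `rejects` (data frame of rejected rows with a `reason` column) and
#'   `n_rows` (input row count).
#' @export
read_primary_table <- function(path, dialect = default_dialect(), dec = ".") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, dec = dec,
                         check.names = FALSE)
  mandatory <- c("dataset_id", "study_id", "species", "trait", "factor",
                 "treatment_value", "male_mean", "female_mean")
  for (f in mandatory) {
    if (!dialect[[f]] %in% names(raw))
      stop("missing mandatory column '", dialect[[f]], "' (field ", f, ")")
  }
  get_col <- function(f, default = NA) {
    nm <- if (f %in% names(dialect)) dialect[[f]] else NULL
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else rep(default, nrow(raw))
  }
  tab <- data.frame(
    dataset_id = as.character(get_col("dataset_id")),
    study_id = as.character(get_col("study_id")),
    species = as.character(get_col("species")),
    order_name = as.character(get_col("order_name", NA_character_)),
    trait = as.character(get_col("trait")),
    factor = as.character(get_col("factor")),
    treatment_value = get_col("treatment_value"),
    male_mean = as.numeric(get_col("male_mean")),
    male_se = as.numeric(get_col("male_se", NA_real_)),
    female_mean = as.numeric(get_col("female_mean")),
    female_se = as.numeric(get_col("female_se", NA_real_)),
    stringsAsFactors = FALSE)
  group_primary_rows(tab)
}

#' Group validated treatment rows into primary datasets
#'
#' Workhorse behind [read_primary_table()]; exported so simulated corpora in
#' data-frame form follow the identical validation path.
#'
#' @param tab Data frame in the internal row schema (see [read_primary_table()]).
#' @return Same structure as [read_primary_table()].
#' @export
group_primary_rows <- function(tab) {
  n_rows <- nrow(tab)
  reason <- rep(NA_character_, n_rows)
  bad_mean <- !is.finite(tab$male_mean) | !is.finite(tab$female_mean) |
    tab$male_mean <= 0 | tab$female_mean <= 0
  reason[bad_mean] <- "non-positive or missing development-time mean"
  bad_se <- !bad_mean &
    ((!is.na(tab$male_se) & tab$male_se < 0) |
       (!is.na(tab$female_se) & tab$female_se < 0))
  reason[bad_se] <- "negative standard error"

  keep <- is.na(reason)
  datasets <- list()
  for (id in unique(tab$dataset_id[keep])) {
    idx <- which(keep & tab$dataset_id == id)
    sub <- tab[idx, , drop = FALSE]
    if (anyDuplicated(sub$treatment_value)) {
      reason[idx] <- "duplicate (dataset_id, treatment_value)"
      next
    }
    if (nrow(sub) < 2L) {
      reason[idx] <- "fewer than 2 valid treatments"
      next
    }
    datasets[[id]] <- primary_dataset(
      dataset_id = id, study_id = sub$study_id[1L], species = sub$species[1L],
      order_name = sub$order_name[1L], trait = sub$trait[1L],
      factor = sub$factor[1L],
      records = sub[, c("treatment_value", "male_mean", "male_se",
                        "female_mean", "female_se")])
  }
  rejects <- cbind(tab[!is.na(reason), , drop = FALSE],
                   reason = reason[!is.na(reason)])
  rownames(rejects) <- NULL
  stopifnot(sum(vapply(datasets, function(d) d$k, 1L)) + nrow(rejects) == n_rows)
  list(datasets = datasets, rejects = rejects, n_rows = n_rows)
}

#' Apply the corpus inclusion rules
#'
#' Datasets need at least two treatments; datasets lacking any standard error
#' are kept for descriptive summaries only ("qualitative-only") because the
#' bootstrap weight cannot be computed for them. The classification is pure
#' and idempotent.
#'
#' @param datasets List of [primary_dataset] objects.
#' @return List with `included` (quantitative datasets), `qualitative`
#'   (SE-less datasets, descriptive use only) and `excluded` (data frame of
#'   dataset_id + reason).
#' @export
apply_inclusion_rules <- function(datasets) {
  included <- list(); qualitative <- list()
  ex_id <- character(); ex_reason <- character()
  for (d in datasets) {
    if (d$k < 2L) {   # unreachable via the constructor; kept for raw lists
      ex_id <- c(ex_id, d$dataset_id)
      ex_reason <- c(ex_reason, "fewer than 2 treatments")
    } else if (!d$has_se) {
      qualitative[[d$dataset_id]] <- d
    } else {
      included[[d$dataset_id]] <- d
    }
  }
  list(included = included, qualitative = qualitative,
       excluded = data.frame(dataset_id = ex_id, reason = ex_reason,
                             stringsAsFactors = FALSE))
}

#' Read a phylogeny from a Newick file
#'
#' @param path Newick file. Tip labels must be unique; polytomies are
#'   preserved (Open Tree topologies contain them); branch lengths retained
#'   when present, else flagged absent.
#' @return An [ape::read.tree] `phylo` object with attribute
#'   `has_branch_lengths`.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable Newick in '", path,
                                            "': ", conditionMessage(e)))
  if (is.null(tree)) stop("unparseable Newick in '", path, "'")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  attr(tree, "has_branch_lengths") <- !is.null(tree$edge.length)
  tree
}

#' Link datasets to phylogeny tips
#'
#' Species missing from the tree may be represented by a congeneric (or, as a
#' fallback, same-tribe) substitute tip supplied in `mapping`; substitutions
#' are logged in the returned table.
#'
#' @param datasets List of [primary_dataset] objects.
#' @param tree A `phylo` object.
#' @param mapping Optional data frame with columns `data_species`, `tree_tip`
#'   and optionally `substitution_kind` (`exact`, `congener`, `tribe`).
#'   Species not listed are matched to identically named tips.
#' @param strict If `TRUE` (default), any species that resolves to no tip
#'   aborts with the offending names; if `FALSE` they are listed in
#'   `$unmapped` and their datasets dropped from `$datasets`.
#' @return List with `datasets` (each gains a `tree_tip` field), `table`
#'   (species, tip, kind) and `unmapped`.
#' @export
resolve_species <- function(datasets, tree, mapping = NULL, strict = TRUE) {
  if (!is.null(mapping)) {
    stopifnot(all(c("data_species", "tree_tip") %in% names(mapping)))
    if (anyDuplicated(mapping$data_species))
      stop("mapping lists a species more than once")
    bad <- setdiff(mapping$tree_tip, tree$tip.label)
    if (length(bad))
      stop("mapping names tips absent from the tree: ", paste(bad, collapse = ", "))
  }
  species <- unique(vapply(datasets, function(d) d$species, character(1)))
  tip <- character(length(species)); kind <- character(length(species))
  for (i in seq_along(species)) {
    sp <- species[i]
    j <- if (!is.null(mapping)) match(sp, mapping$data_species) else NA_integer_
    if (!is.na(j)) {
      tip[i] <- mapping$tree_tip[j]
      kind[i] <- if ("substitution_kind" %in% names(mapping))
        mapping$substitution_kind[j] else "mapped"
    } else if (sp %in% tree$tip.label) {
      tip[i] <- sp; kind[i] <- "exact"
    } else {
      tip[i] <- NA_character_; kind[i] <- "unmapped"
    }
  }
  unmapped <- species[is.na(tip)]
  if (length(unmapped) && strict)
    stop("species not resolvable to a tree tip: ", paste(unmapped, collapse = ", "))
  tab <- data.frame(data_species = species, tree_tip = tip,
                    substitution_kind = kind, stringsAsFactors = FALSE)
  out <- list()
  for (d in datasets) {
    t <- tab$tree_tip[match(d$species, tab$data_species)]
    if (is.na(t)) next
    d$tree_tip <- t
    out[[d$dataset_id]] <- d
  }
  list(datasets = out, table = tab, unmapped = unmapped)
}

#' Write / read the effect-size table
#'
#' Round-trip safe: all numeric fields are written at full precision
#' (`digits = 17`) so a re-read reproduces them bit-for-bit.
#'
#' @param effects Effect-size data frame (see [compute_effects()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_table <- function(effects, path) {
  fmt <- effects
  num <- vapply(fmt, is.numeric, TRUE)
  for (j in which(num)) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  for (j in which(num)) fmt[[j]][fmt[[j]] == "NA"] <- ""
  utils::write.csv(fmt, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_effect_table
#' @export
read_effect_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  numcols <- c("k", "ln_slope", "r_mf", "sdtd", "gradient_length",
               "boot_sd", "weight")
  for (j in intersect(numcols, names(tab))) tab[[j]] <- as.numeric(tab[[j]])
  if ("k" %in% names(tab)) tab$k <- as.integer(tab$k)
  tab
}
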