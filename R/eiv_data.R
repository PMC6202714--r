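# Valid indicator indices and their score ranges. F (moisture) runs to 12 in
# the UK/Ireland tables (aquatics); S admits 0 for non-halophytes.
EIV_INDICES <- c("F", "L", "N", "R", "S")
EIV_RANGES <- list(
  F = c(1L, 12L), L = c(1L, 9L), N = c(1L, 9L), R = c(1L, 9L), S = c(0L, 9L)
)

#' Normalize species names for joining
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs and
#' case-folds. Used as the join key throughout; original spellings are kept
#' in outputs.
#'
#' @param x character vector of species names.
#' @return character vector of normalized names.
#' @export
normalize_species <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' Read an indicator-value lookup table
#'
#' Reads a CSV with a `species` column and one integer column per indicator
#' index (any subset of F, L, N, R, S; empty cells mark missing scores).
#' Species names are normalized for joining; duplicated rows whose scores
#' agree are collapsed, conflicting duplicates are an error.
#'
#' @param path path to the CSV file.
#' @param indices character vector of index columns to keep.
#' @return an `eiv_table`: data frame with columns `species` (original
#'   spelling) and one column per requested index, with attributes
#'   `missing_counts` (named integer vector) and `key` (normalized names).
#' @export
load_eiv_table <- function(path, indices = EIV_INDICES) {
  indices <- match.arg(indices, EIV_INDICES, several.ok = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"species" %in% names(raw)) {
    stop("EIV file must have a 'species' column: ", path)
  }
  missing_idx <- setdiff(indices, names(raw))
  if (length(missing_idx)) {
    stop("EIV file lacks requested index column(s): ",
         paste(missing_idx, collapse = ", "))
  }
  tab <- raw[, c("species", indices), drop = FALSE]
  tab$.key <- normalize_species(tab$species)
  for (ix in indices) {
    v <- tab[[ix]]
    v[v %in% c("", "NA")] <- NA
    v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & (v != round(v) |
                              v < EIV_RANGES[[ix]][1] | v > EIV_RANGES[[ix]][2]))
    if (length(bad)) {
      stop(sprintf("out-of-range %s score at row %d (species '%s'): %s",
                   ix, bad[1], tab$species[bad[1]], tab[[ix]][bad[1]]))
    }
    tab[[ix]] <- as.integer(v)
  }
  if (anyDuplicated(tab$.key)) {
    split_rows <- split(seq_len(nrow(tab)), tab$.key)
    keep <- integer(0)
    for (rows in split_rows) {
      if (length(rows) > 1L) {
        sub <- tab[rows, indices, drop = FALSE]
        conflicting <- vapply(sub, function(col) {
          length(unique(col[!is.na(col)])) > 1L
        }, logical(1))
        if (any(conflicting)) {
          stop(sprintf("conflicting scores for species '%s' (index %s)",
                       tab$species[rows[1]],
                       paste(indices[conflicting], collapse = ", ")))
        }
        # merge agreeing duplicates, filling missing cells where one row has it
        for (ix in indices) {
          vals <- tab[rows, ix]
          tab[rows[1], ix] <- if (all(is.na(vals))) NA_integer_ else
            vals[!is.na(vals)][1]
        }
      }
      keep <- c(keep, rows[1])
    }
    tab <- tab[sort(keep), , drop = FALSE]
  }
  out <- tab[, c("species", indices), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "key") <- tab$.key
  attr(out, "missing_counts") <-
    vapply(out[indices], function(col) sum(is.na(col)), integer(1))
  class(out) <- c("eiv_table", "data.frame")
  out
}

#' Read species occurrence records
#'
#' Reads a CSV with header `plot,period,species`; `period` must be 1 or 2.
#' Duplicate (plot, period, species) triples are dropped (presence/absence
#' semantics) and the number removed is recorded.
#'
#' @param path path to the CSV file.
#' @return an `occurrence_set` data frame with columns `plot`, `period`,
#'   `species` and attribute `n_deduplicated`.
#' @export
load_occurrences <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot", "period", "species")
  if (!all(need %in% names(raw))) {
    stop("occurrence file must have columns plot,period,species: ", path)
  }
  as_occurrence_set(raw[, need])
}

#' Construct an occurrence set from a data frame
#'
#' @param df data frame with columns `plot`, `period`, `species`.
#' @return an `occurrence_set` (see [load_occurrences()]).
#' @export
as_occurrence_set <- function(df) {
  occ <- data.frame(plot = as.character(df$plot),
                    period = as.integer(df$period),
                    species = as.character(df$species),
                    stringsAsFactors = FALSE)
  if (!all(occ$period %in% c(1L, 2L))) {
    stop("period must be 1 or 2")
  }
  key <- paste(occ$plot, occ$period, normalize_species(occ$species), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message(sum(dup), " duplicate occurrence record(s) removed")
    occ <- occ[!dup, , drop = FALSE]
  }
  rownames(occ) <- NULL
  attr(occ, "n_deduplicated") <- sum(dup)
  class(occ) <- c("occurrence_set", "data.frame")
  occ
}

#' Read a plot design table
#'
#' Reads a CSV with header `plot,habitat[,area_m2,lat,lon]`. Each plot must
#' carry exactly one habitat label; habitat labels form the grouping factor
#' of the group-level models.
#'
#' @param path path to the CSV file.
#' @return a `plot_design` data frame with columns `plot`, `habitat` and any
#'   of `area_m2`, `lat`, `lon` present in the file.
#' @export
load_plot_design <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("plot", "habitat") %in% names(raw))) {
    stop("design file must have columns plot,habitat: ", path)
  }
  as_plot_design(raw)
}

#' Construct a plot design from a data frame
#'
#' @param df data frame with columns `plot`, `habitat` (and optionally
#'   `area_m2`, `lat`, `lon`).
#' @return a `plot_design` data frame.
#' @export
as_plot_design <- function(df) {
  keep <- intersect(c("plot", "habitat", "area_m2", "lat", "lon"), names(df))
  des <- as.data.frame(df[, keep, drop = FALSE], stringsAsFactors = FALSE)
  des$plot <- as.character(des$plot)
  des$habitat <- as.character(des$habitat)
  if (anyDuplicated(des$plot)) {
    bad <- des$plot[duplicated(des$plot)][1]
    stop("plot appears more than once in design: ", bad)
  }
  if ("area_m2" %in% names(des) &&
      any(!is.na(des$area_m2) & des$area_m2 <= 0)) {
    stop("area_m2 must be positive where present")
  }
  rownames(des) <- NULL
  class(des) <- c("plot_design", "data.frame")
  des
}

#' Assemble the long-format model frame for one indicator index
#'
#' Joins occurrence records to the indicator table for one index and attaches
#' the habitat grouping from the plot design. One row per scored occurrence;
#' occurrences of species without a score for the chosen index are dropped
#' and reported. Rows are ordered deterministically by (plot, period,
#' species).
#'
#' @param occurrences an `occurrence_set`.
#' @param eiv an `eiv_table`.
#' @param design a `plot_design`; every occurrence plot must appear here.
#' @param index one of `"F"`, `"L"`, `"N"`, `"R"`, `"S"`.
#' @return a `model_frame`: data frame with columns `y` (score), `plot`,
#'   `period`, `x` (0/1 period indicator), `j` (plot index), `habitat`,
#'   `k` (habitat index), `species`; attributes `index`, `plot_levels`,
#'   `habitat_levels`, `habitat_of_plot` (k for each j) and `drop_report`
#'   (data frame of dropped species and counts).
#' @export
build_model_frame <- function(occurrences, eiv, design, index) {
  index <- match.arg(index, EIV_INDICES)
  if (!index %in% names(eiv)) {
    stop("EIV table has no column for index ", index)
  }
  occ <- occurrences
  missing_plots <- setdiff(unique(occ$plot), design$plot)
  if (length(missing_plots)) {
    stop("plot(s) in occurrences but absent from design: ",
         paste(utils::head(missing_plots, 5), collapse = ", "))
  }
  key <- attr(eiv, "key")
  if (is.null(key)) key <- normalize_species(eiv$species)
  score <- eiv[[index]][match(normalize_species(occ$species), key)]
  dropped <- is.na(score)
  drop_report <- data.frame(species = character(0), n = integer(0))
  if (any(dropped)) {
    tab <- table(occ$species[dropped])
    drop_report <- data.frame(species = names(tab), n = as.integer(tab),
                              stringsAsFactors = FALSE)
    drop_report <- drop_report[order(drop_report$species), , drop = FALSE]
    rownames(drop_report) <- NULL
  }
  fr <- data.frame(y = as.numeric(score[!dropped]),
                   plot = occ$plot[!dropped],
                   period = occ$period[!dropped],
                   species = occ$species[!dropped],
                   stringsAsFactors = FALSE)
  if (nrow(fr) == 0L) {
    stop("no occurrence has a score for index ", index)
  }
  fr <- fr[order(fr$plot, fr$period, normalize_species(fr$species)), ,
           drop = FALSE]
  habitat_map <- stats::setNames(design$habitat, design$plot)
  fr$habitat <- unname(habitat_map[fr$plot])
  new_model_frame(fr, index = index, drop_report = drop_report)
}

# Internal constructor: finalizes indices j, k and x from plot/period/habitat
# columns and attaches metadata.
new_model_frame <- function(fr, index, drop_report = NULL) {
  plot_levels <- sort(unique(fr$plot))
  fr$j <- match(fr$plot, plot_levels)
  hab_of_plot_lab <- vapply(plot_levels, function(p) {
    fr$habitat[match(p, fr$plot)]
  }, character(1))
  habitat_levels <- sort(unique(hab_of_plot_lab))
  habitat_of_plot <- match(hab_of_plot_lab, habitat_levels)
  fr$k <- habitat_of_plot[fr$j]
  fr$x <- as.integer(fr$period == 2L)
  fr <- fr[, c("y", "plot", "period", "x", "j", "habitat", "k", "species")]
  rownames(fr) <- NULL
  attr(fr, "index") <- index
  attr(fr, "plot_levels") <- plot_levels
  attr(fr, "habitat_levels") <- habitat_levels
  attr(fr, "habitat_of_plot") <- habitat_of_plot
  attr(fr, "drop_report") <- drop_report
  class(fr) <- c("model_frame", "data.frame")
  fr
}

#' @export
print.model_frame <- function(x, ...) {
  cat(sprintf(
    "model_frame: %d observations, %d plots, %d habitats, index %s\n",
    nrow(x), length(attr(x, "plot_levels")),
    length(attr(x, "habitat_levels")), attr(x, "index")))
  dr <- attr(x, "drop_report")
  if (!is.null(dr) && nrow(dr)) {
    cat(sprintf("  %d occurrence(s) of %d unscored species dropped\n",
                sum(dr$n), nrow(dr)))
  }
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("  ...\n")
  invisible(x)
}

#' Raw plot mean scores per period
#'
#' The classical "community mean" point estimates: per (plot, period), the
#' unweighted arithmetic mean of the indicator scores of recorded species.
#'
#' @param frame a `model_frame`.
#' @return a `raw_means` data frame with columns `plot`, `period`, `mean`,
#'   `n`, ordered by (plot, period).
#' @export
plot_raw_means <- function(frame) {
  if (nrow(frame) == 0L) stop("empty model frame")
  agg <- stats::aggregate(frame$y, by = list(plot = frame$plot,
                                             period = frame$period),
                          FUN = mean)
  cnt <- stats::aggregate(frame$y, by = list(plot = frame$plot,
                                             period = frame$period),
                          FUN = length)
  out <- data.frame(plot = agg$plot, period = agg$period,
                    mean = agg$x, n = as.integer(cnt$x),
                    stringsAsFactors = FALSE)
  out <- out[order(out$plot, out$period), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "index") <- attr(frame, "index")
  class(out) <- c("raw_means", "data.frame")
  out
}

#' Write a model frame to the canonical long-format CSV
#'
#' Columns `y,plot,period,habitat,species,index`; [read_model_frame()]
#' reproduces the frame exactly.
#'
#' @param frame a `model_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_frame <- function(frame, path) {
  out <- data.frame(y = frame$y, plot = frame$plot, period = frame$period,
                    habitat = frame$habitat, species = frame$species,
                    index = attr(frame, "index"), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a model frame written by [write_model_frame()]
#'
#' @param path path to the long-format CSV.
#' @return a `model_frame`.
#' @export
read_model_frame <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("y", "plot", "period", "habitat", "species", "index")
  if (!all(need %in% names(raw))) {
    stop("not a model-frame CSV (need columns ",
         paste(need, collapse = ","), "): ", path)
  }
  index <- unique(raw$index)
  if (length(index) != 1L) stop("model-frame CSV mixes indices")
  fr <- data.frame(y = as.numeric(raw$y), plot = as.character(raw$plot),
                   period = as.integer(raw$period),
                   habitat = as.character(raw$habitat),
                   species = as.character(raw$species),
                   stringsAsFactors = FALSE)
  fr <- fr[order(fr$plot, fr$period, normalize_species(fr$species)), ,
           drop = FALSE]
  new_model_frame(fr, index = index)
}
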