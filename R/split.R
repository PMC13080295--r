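# Report-level grouped dataset splitting. All items derived from the same
# report must land in the same partition, so the assignment works on
# report groups and targets item counts.

round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Split items into train/test/validation at the report level
#'
#' Every item (for example a question--answer pair) is tied to a source
#' report; all items sharing a report are assigned to the same partition.
#' With singleton groups the partition sizes follow the 60/30/10 rule with
#' round-half-away-from-zero on the train and test counts and the
#' remainder going to validation (so 4095 items split 2457/1229/409 and
#' 1488 split 893/446/149). With multi-item groups, groups are assigned
#' greedily, largest first, to the partition with the largest remaining
#' deficit relative to those targets.
#'
#' @param item_to_report named character vector: names are item ids,
#'   values the owning report ids. A bare character vector of report ids
#'   (one item per report) is also accepted.
#' @param ratios numeric length-3 vector `(train, test, validation)`
#'   summing to 1. Default `c(0.6, 0.3, 0.1)`.
#' @param seed integer; controls tie-breaking order among equally sized
#'   groups.
#' @return Object of class `ae_split`: list with `assignment` (named
#'   character vector report_id -> partition), `items` (named character
#'   vector item id -> partition), `sizes` (item counts per partition),
#'   `ratios`, `seed`.
#' @export
#' @examples
#' sp <- split_dataset(as.character(1:10), seed = 1)
#' sp$sizes  # 6 / 3 / 1
split_dataset <- function(item_to_report, ratios = c(0.6, 0.3, 0.1),
                          seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    stop("ratios must be three numbers summing to 1")
  if (length(item_to_report) < 3L)
    stop("infeasible split: fewer reports (", length(item_to_report),
         ") than partitions (3)")
  if (is.null(names(item_to_report)))
    names(item_to_report) <- paste0("item", seq_along(item_to_report))
  report_ids <- as.character(item_to_report)
  groups <- split(names(item_to_report), report_ids)
  n_reports <- length(groups)
  if (n_reports < 3L)
    stop("infeasible split: fewer reports (", n_reports,
         ") than partitions (3)")
  n_items <- length(item_to_report)
  target <- c(train = round_half_away(ratios[1] * n_items),
              test  = round_half_away(ratios[2] * n_items))
  target <- c(target, validation = n_items - sum(target))
  if (any(target < 0)) stop("ratios produce a negative partition size")

  sizes <- vapply(groups, length, integer(1))
  set.seed(as.integer(seed))
  ord <- order(-sizes, runif(length(sizes)))   # largest first, seeded ties
  filled <- c(train = 0L, test = 0L, validation = 0L)
  part_names <- names(filled)
  assignment <- character(n_reports)
  names(assignment) <- names(groups)
  for (g in ord) {
    deficit <- target - filled
    # partition whose deficit the group reduces most without overshoot bias
    score <- deficit - sizes[g] / 2
    pick <- part_names[which.max(score)]
    assignment[names(groups)[g]] <- pick
    filled[pick] <- filled[pick] + sizes[g]
  }
  items <- assignment[report_ids]
  names(items) <- names(item_to_report)
  structure(list(assignment = assignment, items = items,
                 sizes = c(table(factor(items, levels = part_names))),
                 ratios = ratios, seed = as.integer(seed)),
            class = "ae_split")
}

#' @export
print.ae_split <- function(x, ...) {
  cat("<ae_split> ", sum(x$sizes), " items over ", length(x$assignment),
      " reports: ", paste(names(x$sizes), x$sizes, sep = "=",
                          collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a split assignment to CSV
#'
#' @param split an `ae_split`.
#' @param path output CSV path (`report_id`, `partition`).
#' @export
write_split_csv <- function(split, path) {
  df <- data.frame(report_id = names(split$assignment),
                   partition = unname(split$assignment),
                   stringsAsFactors = FALSE)
  write.csv(df[order(df$report_id), ], path, row.names = FALSE)
  invisible(path)
}
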