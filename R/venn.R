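#' Venn partition of regulated sets across two comparisons
#'
#' Partitions the union of four regulated sets (up/down in comparison A,
#' up/down in comparison B) into eight pairwise-disjoint cells: common
#' up, common down, unique-to-A up/down, unique-to-B up/down, and the two
#' discordant cells (up in one comparison, down in the other). "Unique
#' to A" excludes features regulated in B in either direction, so that
#' discordant features occupy only their own cells and the marginal
#' identity |A_up| = common_up + unique_A_up + discordant_A_up_B_down
#' holds exactly.
#'
#' @param A_up,A_down,B_up,B_down Character vectors of feature ids; the
#'   up and down set of one comparison must be disjoint.
#' @param labels Length-2 character vector naming the two comparisons.
#' @return An object of class `venn_partition`: list of the eight cells
#'   plus `labels`.
#' @export
venn_partition <- function(A_up, A_down, B_up, B_down,
                           labels = c("A", "B")) {
  A_up <- unique(as.character(A_up)); A_down <- unique(as.character(A_down))
  B_up <- unique(as.character(B_up)); B_down <- unique(as.character(B_down))
  if (length(intersect(A_up, A_down)))
    stop("up/down overlap within comparison ", labels[1], ": ",
         paste(intersect(A_up, A_down), collapse = ", "))
  if (length(intersect(B_up, B_down)))
    stop("up/down overlap within comparison ", labels[2], ": ",
         paste(intersect(B_up, B_down), collapse = ", "))
  B_any <- union(B_up, B_down)
  A_any <- union(A_up, A_down)
  structure(list(
    labels = labels,
    common_up = intersect(A_up, B_up),
    unique_A_up = setdiff(A_up, B_any),
    unique_B_up = setdiff(B_up, A_any),
    common_down = intersect(A_down, B_down),
    unique_A_down = setdiff(A_down, B_any),
    unique_B_down = setdiff(B_down, A_any),
    discordant_A_up_B_down = intersect(A_up, B_down),
    discordant_A_down_B_up = intersect(A_down, B_up)),
    class = "venn_partition")
}

venn_cells <- c("common_up", "unique_A_up", "unique_B_up",
                "common_down", "unique_A_down", "unique_B_down",
                "discordant_A_up_B_down", "discordant_A_down_B_up")

#' Cell counts and marginal totals of a Venn partition
#'
#' @param partition A [venn_partition()].
#' @return List with `counts` (named integer vector over the eight
#'   cells) and `marginals` (|A_up|, |A_down|, |B_up|, |B_down|, total).
#' @export
overlap_summary <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  counts <- vapply(venn_cells, function(cell)
    length(partition[[cell]]), integer(1))
  marginals <- c(
    A_up = counts[["common_up"]] + counts[["unique_A_up"]] +
      counts[["discordant_A_up_B_down"]],
    A_down = counts[["common_down"]] + counts[["unique_A_down"]] +
      counts[["discordant_A_down_B_up"]],
    B_up = counts[["common_up"]] + counts[["unique_B_up"]] +
      counts[["discordant_A_down_B_up"]],
    B_down = counts[["common_down"]] + counts[["unique_B_down"]] +
      counts[["discordant_A_up_B_down"]],
    total = sum(counts))
  list(counts = counts, marginals = marginals)
}

#' @export
print.venn_partition <- function(x, ...) {
  s <- overlap_summary(x)
  cat(sprintf("venn_partition: %s vs %s (%d features)\n",
              x$labels[1], x$labels[2], s$marginals[["total"]]))
  for (cell in venn_cells)
    cat(sprintf("  %-24s %d\n", cell, s$counts[[cell]]))
  invisible(x)
}
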