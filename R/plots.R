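# Report rendering. Every figure has a companion *_table() function
# returning exactly the numbers plotted; tests assert on the tables,
# never on rendered pixels.

#' Zero-filled trend table over the union of years
#'
#' All series are aligned on the union of observed years; years missing
#' from a series are filled with zero, which is also how they are drawn.
#'
#' @param trends A `corpus`/`year`/`n` tibble (e.g. `res$trends`).
#' @return The zero-filled tibble, one row per corpus x year.
#' @export
trend_plot_table <- function(trends) {
  if (nrow(trends) == 0L) return(trends)
  yrs <- seq(min(trends$year), max(trends$year))
  filled <- tidyr::complete(trends, corpus = unique(trends$corpus),
                            year = yrs, fill = list(n = 0L))
  dplyr::arrange(filled, .data$corpus, .data$year)
}

#' Publication-trend line plot
#'
#' One line per corpus over the union of years (zero-filled).
#'
#' @param trends A `corpus`/`year`/`n` tibble.
#' @return A ggplot; its `data` is [trend_plot_table()] of the input.
#' @export
plot_trends <- function(trends) {
  if (nrow(trends) == 0L) stop("no trend series to plot", call. = FALSE)
  ggplot2::ggplot(trend_plot_table(trends),
                  ggplot2::aes(x = .data$year, y = .data$n,
                               colour = .data$corpus)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "publication year", y = "articles",
                  colour = NULL,
                  title = "miRNA publications per year") +
    ggplot2::theme_minimal()
}

#' Top-n aggregate ranking table and bar chart
#'
#' @param aggregate A `family`/`n` tibble (e.g. `res$aggregate`).
#' @param n How many families to keep (default 25).
#' @return `top_aggregate_table()`: a `rank`/`family`/`n` tibble;
#'   `plot_top_families()`: a bar chart of it.
#' @export
top_aggregate_table <- function(aggregate, n = 25) {
  top_families(aggregate, k = n)
}

#' @rdname top_aggregate_table
#' @export
plot_top_families <- function(aggregate, n = 25) {
  tbl <- top_aggregate_table(aggregate, n)
  tbl$family <- factor(tbl$family, levels = rev(tbl$family))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$n, y = .data$family)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "articles (all corpora)", y = NULL,
                  title = sprintf("Top %d most-published miRNA families",
                                  nrow(tbl))) +
    ggplot2::theme_minimal()
}

#' Breadth chart: corpora per family
#'
#' @param breadth A `family`/`n_corpora` tibble (e.g. `res$breadth`),
#'   already sorted by decreasing breadth then family index.
#' @return A bar chart whose `data` is the input table.
#' @export
plot_breadth <- function(breadth) {
  tbl <- breadth
  tbl$family <- factor(tbl$family, levels = rev(tbl$family))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$n_corpora, y = .data$family)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "corpora with family in top-k", y = NULL,
                  title = "Cross-corpus breadth of top-ranked families") +
    ggplot2::theme_minimal()
}

#' Donut wedge table and per-corpus donut charts
#'
#' Wedge fractions are each family's article count divided by the sum of
#' the top-k counts of its corpus; wedges follow ranking order.
#'
#' @param rankings A `corpus`/`rank`/`family`/`n` tibble
#'   (e.g. `res$rankings`).
#' @return `donut_table()`: the rankings with a `fraction` column;
#'   `plot_donuts()`: a faceted donut chart.
#' @export
donut_table <- function(rankings) {
  dplyr::mutate(dplyr::group_by(rankings, .data$corpus),
                fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' @rdname donut_table
#' @export
plot_donuts <- function(rankings) {
  tbl <- donut_table(rankings)
  tbl$family <- factor(tbl$family, levels = unique(tbl$family))
  ggplot2::ggplot(tbl, ggplot2::aes(x = 2, y = .data$fraction,
                                    fill = .data$family)) +
    ggplot2::geom_col(width = 1, colour = "white") +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::xlim(0.5, 2.5) +
    ggplot2::facet_wrap(~corpus) +
    ggplot2::labs(fill = NULL, title = "Top miRNA families per corpus") +
    ggplot2::theme_void()
}

#' Co-occurrence heatmaps
#'
#' One heatmap per corpus: rows are the corpus's top-k families
#' (ranking order), columns the dictionary terms grouped by category in
#' the order cell types, cytokines, processes; cells are annotated with
#' integer article counts and the colour scale is anchored at zero.
#'
#' @param cooccurrence A `corpus`/`family`/`category`/`term`/`n` tibble
#'   (e.g. `res$cooccurrence`).
#' @param normalize `"panel"` (default): each corpus panel uses its own
#'   colour maximum; `"global"`: one shared maximum.
#' @return A named list of ggplots, one per corpus; each plot's `data`
#'   holds exactly the plotted counts.
#' @export
plot_cooccurrence <- function(cooccurrence, normalize = c("panel", "global")) {
  normalize <- match.arg(normalize)
  global_max <- max(c(0L, cooccurrence$n))
  purrr::imap(split(cooccurrence,
                    factor(cooccurrence$corpus,
                           levels = unique(cooccurrence$corpus))),
    function(tbl, lbl) {
      tbl$term <- factor(
        tbl$term,
        levels = unique(tbl$term[order(match(tbl$category,
                                             c("cell_type", "cytokine",
                                               "process")))]))
      tbl$family <- factor(tbl$family, levels = rev(unique(tbl$family)))
      top <- if (normalize == "panel") max(c(0L, tbl$n)) else global_max
      ggplot2::ggplot(tbl, ggplot2::aes(x = .data$term, y = .data$family,
                                        fill = .data$n)) +
        ggplot2::geom_tile(colour = "grey80") +
        ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 2.6) +
        ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                     limits = c(0, max(top, 1L))) +
        ggplot2::labs(title = lbl, x = NULL, y = NULL, fill = "articles") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                           hjust = 1,
                                                           vjust = 0.5))
    })
}

slugify <- function(x) {
  gsub("^_+|_+$", "", gsub("[^A-Za-z0-9]+", "_", x))
}

#' Write the full result bundle to disk
#'
#' Emits, under `dir`: one CSV per ranking (`ranking_<corpus>.csv`), per
#' co-occurrence matrix in long form (`cooccurrence_<corpus>.csv`), per
#' trend (`trend_<corpus>.csv`); the aggregate and breadth tables; a
#' machine-readable `manifest.json` (corpus sizes, dictionary hash, k,
#' package version); and, optionally, the figures as PNGs. Output is
#' byte-stable: rerunning on the same result reproduces every table.
#'
#' @param result A `mirmine_result` from [mine_corpora()].
#' @param dir Output directory (created if needed).
#' @param plots If `TRUE`, also render the PNG figures.
#' @return Invisibly, a character vector of the files written.
#' @export
write_report <- function(result, dir, plots = TRUE) {
  stopifnot(inherits(result, "mirmine_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(dir, name)
    readr::write_csv(tbl, path)
    files <<- c(files, path)
  }
  for (lbl in unique(result$corpus_sizes$corpus)) {
    s <- slugify(lbl)
    emit(dplyr::filter(result$rankings, .data$corpus == lbl),
         sprintf("ranking_%s.csv", s))
    emit(dplyr::filter(result$cooccurrence, .data$corpus == lbl),
         sprintf("cooccurrence_%s.csv", s))
    emit(dplyr::filter(result$trends, .data$corpus == lbl),
         sprintf("trend_%s.csv", s))
  }
  emit(result$aggregate, "aggregate_counts.csv")
  emit(result$breadth, "breadth.csv")
  emit(result$corpus_sizes, "corpus_sizes.csv")
  if (nrow(result$shared_pmids)) emit(result$shared_pmids, "shared_pmids.csv")

  manifest <- list(
    tool = "mirmine",
    version = as.character(utils::packageVersion("mirmine")),
    k = result$k,
    keep_reviews = result$keep_reviews,
    dictionary_hash = result$dictionary_hash,
    corpora = result$corpus_sizes
  )
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest_path)

  if (plots) {
    save_plot <- function(p, name, width = 8, height = 5) {
      path <- file.path(dir, name)
      suppressMessages(ggplot2::ggsave(path, p, width = width,
                                       height = height, dpi = 150))
      files <<- c(files, path)
    }
    if (nrow(result$trends)) save_plot(plot_trends(result$trends), "trends.png")
    if (nrow(result$aggregate))
      save_plot(plot_top_families(result$aggregate), "top_families.png",
                height = 7)
    if (nrow(result$breadth))
      save_plot(plot_breadth(result$breadth), "breadth.png")
    if (nrow(result$rankings))
      save_plot(plot_donuts(result$rankings), "donuts.png", height = 7)
    hm <- plot_cooccurrence(result$cooccurrence)
    for (lbl in names(hm)) {
      save_plot(hm[[lbl]], sprintf("heatmap_%s.png", slugify(lbl)),
                width = 10, height = 4)
    }
  }
  invisible(files)
}
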