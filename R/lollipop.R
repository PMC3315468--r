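#' Render clone calls as a lollipop diagram
#'
#' Produces the classic single-molecule bisulfite display: one row per
#' clone, open/filled circles for unmethylated/methylated HCG sites, teal
#' circles for accessible GCH sites, and shading over protected footprints
#' longer than 146 bp. Two renderings are available: a plain-text form that
#' round-trips losslessly through [parse_lollipop()], and a `ggplot2`
#' figure (which can be saved to SVG with `ggplot2::ggsave()`).
#'
#' Text symbols: `M`/`U` methylated/unmethylated HCG, `A`/`I`
#' accessible/inaccessible GCH, `.` missing.
#'
#' @param callsets Non-empty list of [call_clone()] results.
#' @param annotation Shared `site_annotation`.
#' @param format `"text"` (default) or `"ggplot"`.
#' @param window Optional [ndr_window()] drawn on the figure.
#' @param tss Optional TSS position (marked on the figure).
#' @param path Optional output path for the text rendering.
#' @return Character vector of text lines, or a `ggplot` object.
#' @export
render_lollipop <- function(callsets, annotation,
                            format = c("text", "ggplot"),
                            window = NULL, tss = NULL, path = NULL) {
  format <- match.arg(format)
  if (!length(callsets)) stop("empty call table")
  if (format == "text") {
    lines <- lollipop_text(callsets, annotation)
    if (!is.null(path)) writeLines(lines, path)
    return(invisible(lines))
  }
  lollipop_ggplot(callsets, annotation, window = window, tss = tss)
}

lollipop_text <- function(callsets, annotation) {
  site_pos <- c(annotation$hcg_sites, annotation$gch_sites)
  site_type <- c(rep("hcg", length(annotation$hcg_sites)),
                 rep("gch", length(annotation$gch_sites)))
  ord <- order(site_pos)
  header <- c(
    sprintf("#lollipop region=%s", annotation$region_id),
    sprintf("#sites %s",
            paste(sprintf("%s:%d", site_type[ord], site_pos[ord]),
                  collapse = " ")))
  sym_hcg <- c(methylated = "M", unmethylated = "U", missing = ".")
  sym_gch <- c(accessible = "A", inaccessible = "I", missing = ".")
  rows <- vapply(callsets, function(cs) {
    sym <- c(sym_hcg[as.character(cs$hcg_calls)],
             sym_gch[as.character(cs$gch_calls)])[ord]
    paste(cs$clone_id, cs$strand, paste(sym, collapse = ""), sep = "\t")
  }, character(1L))
  c(header, unname(rows))
}

#' Parse a text lollipop rendering back into a call table
#'
#' Inverse of the `"text"` format of [render_lollipop()].
#'
#' @param lines Character vector of lines (or a file path of length 1 that
#'   exists on disk).
#' @return List: `region_id`, `sites` (data.frame type/pos), and `calls`
#'   (data.frame clone_id, strand, one column per site symbol).
#' @export
parse_lollipop <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  stopifnot(startsWith(lines[1L], "#lollipop"),
            startsWith(lines[2L], "#sites"))
  region_id <- sub("^#lollipop region=", "", lines[1L])
  toks <- strsplit(sub("^#sites ", "", lines[2L]), " ", fixed = TRUE)[[1L]]
  parts <- strsplit(toks, ":", fixed = TRUE)
  sites <- data.frame(type = vapply(parts, `[[`, "", 1L),
                      pos = as.integer(vapply(parts, `[[`, "", 2L)),
                      stringsAsFactors = FALSE)
  body <- strsplit(lines[-(1:2)], "\t", fixed = TRUE)
  sym <- t(vapply(body, function(b) strsplit(b[3L], "")[[1L]],
                  character(nrow(sites))))
  if (nrow(sites) == 1L) sym <- t(sym)
  calls <- data.frame(
    clone_id = vapply(body, `[[`, "", 1L),
    strand = vapply(body, `[[`, "", 2L),
    sym, stringsAsFactors = FALSE)
  names(calls)[-(1:2)] <- paste0(sites$type, "_", sites$pos)
  list(region_id = region_id, sites = sites, calls = calls)
}

lollipop_ggplot <- function(callsets, annotation, window = NULL, tss = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("the 'ggplot2' package is required for format = \"ggplot\"")
  }
  rows <- lapply(seq_along(callsets), function(i) {
    cs <- callsets[[i]]
    data.frame(
      y = i,
      pos = c(annotation$hcg_sites, annotation$gch_sites),
      type = c(rep("HCG", length(cs$hcg_calls)),
               rep("GCH", length(cs$gch_calls))),
      call = c(as.character(cs$hcg_calls), as.character(cs$gch_calls)),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[df$call != "missing", ]
  df$fill <- with(df, ifelse(type == "HCG",
                             ifelse(call == "methylated", "black", "white"),
                             ifelse(call == "accessible", "#008080", "grey85")))
  shade <- do.call(rbind, lapply(seq_along(callsets), function(i) {
    seg <- segment_clone(callsets[[i]], annotation)
    seg <- seg[seg$state == "protected" & seg$span > 146L, , drop = FALSE]
    if (!nrow(seg)) return(NULL)
    data.frame(y = i, start = seg$start, end = seg$end)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = pos, y = y))
  if (!is.null(shade)) {
    p <- p + ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE, fill = "pink", alpha = 0.6,
      ggplot2::aes(xmin = start, xmax = end,
                   ymin = y - 0.4, ymax = y + 0.4))
  }
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect", xmin = window$start,
                               xmax = window$end, ymin = 0.4,
                               ymax = length(callsets) + 0.6,
                               fill = NA, colour = "darkgreen",
                               linetype = 2)
  }
  if (!is.null(tss)) {
    p <- p + ggplot2::geom_vline(xintercept = tss, linetype = 3)
  }
  p + ggplot2::geom_point(ggplot2::aes(shape = type), fill = df$fill,
                          size = 2) +
    ggplot2::scale_shape_manual(values = c(HCG = 21, GCH = 23)) +
    ggplot2::scale_y_reverse(breaks = seq_along(callsets),
                             labels = vapply(callsets, `[[`, "", "clone_id")) +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal()
}
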