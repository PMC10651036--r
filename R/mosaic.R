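# Ternary landscape-mosaic classifiers.
#
# A window whose included pixels are all coded 1, 2 or 3 has a three-part
# composition (p1, p2, p3) on the unit simplex; the mosaic metrics map that
# composition to a nominal class code. Two partitions are provided:
#
# * 19-class (coarse): 3 pure-corner classes (one proportion equals 1) plus
#   the 16 regions cut out of the simplex by the 10% and 60% threshold
#   lines on each axis -- an axis is "dominant" at >= 60% and "present" at
#   >= 10%. (Twelve regions have a dominant axis, four have none; fewer
#   than two present axes is arithmetically impossible.)
# * 103-class (fine): 3 pure-corner classes plus the 100 triangular cells
#   of the 10-percent mesh of the simplex (55 upward and 45 downward
#   cells).
#
# Codes are assigned in a fixed canonical order (corners first, then
# dominant/upward cells, then the rest) so outputs are stable across
# releases; gsc_mosaic_legend() spells out every code.

.gsc_eps <- 1e-9

# 103-class cell code lookups, built once: up cells i+j+k = 9 (codes 4..58),
# down cells i+j+k = 8 (codes 59..103), lexicographic in (i, j).
gsc_mosaic103_tables <- function() {
  up <- matrix(NA_integer_, 10L, 10L); dn <- matrix(NA_integer_, 10L, 10L)
  code <- 3L
  for (i in 0:9) for (j in 0:(9 - i)) { code <- code + 1L; up[i + 1L, j + 1L] <- code }
  for (i in 0:8) for (j in 0:(8 - i)) { code <- code + 1L; dn[i + 1L, j + 1L] <- code }
  list(up = up, down = dn)
}
.gsc_m103 <- gsc_mosaic103_tables()

gsc_classify_mosaic1 <- function(p1, p2, p3, variant) {
  if (is.na(p1) || is.na(p2) || is.na(p3)) return(NA_real_)
  if (abs(p1 + p2 + p3 - 1) > .gsc_eps) return(NA_real_)
  p <- c(p1, p2, p3)
  pure <- which(p >= 1 - .gsc_eps)
  if (length(pure)) return(as.numeric(pure[1L]))
  if (variant == 19L) {
    ge <- function(a, b) a >= b - .gsc_eps
    dom <- which(vapply(p, ge, TRUE, b = 0.6))
    pres <- vapply(p, ge, TRUE, b = 0.1)
    if (length(dom)) {
      d <- dom[1L]                      # at most one axis can reach 60%
      others <- setdiff(1:3, d)
      sub <- sum(c(1L, 2L) * pres[others])  # 0, 1, 2 or 3
      return(3 + (d - 1L) * 4L + sub + 1)
    }
    combos <- list(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, TRUE),
                   c(FALSE, TRUE, TRUE), c(TRUE, TRUE, TRUE))
    for (w in seq_along(combos))
      if (identical(unname(pres), combos[[w]])) return(15 + w)
    return(NA_real_)  # unreachable on the valid simplex
  }
  # 103-class: locate the triangular cell of the 10%-step mesh
  snap <- function(z) if (abs(z - round(z)) < 1e-7) round(z) else z
  a <- snap(10 * p1); b <- snap(10 * p2); cc <- snap(10 * p3)
  i <- floor(a); j <- floor(b); k <- floor(cc)
  s <- i + j + k
  if (s == 10) {                        # mesh vertex: fold into an up cell
    m <- which.max(c(i, j, k))
    if (m == 1L) i <- i - 1L else if (m == 2L) j <- j - 1L else k <- k - 1L
    s <- 9L
  }
  if (s == 9) return(as.numeric(.gsc_m103$up[i + 1L, j + 1L]))
  as.numeric(.gsc_m103$down[i + 1L, j + 1L])
}

#' Classify a ternary composition into a landscape-mosaic class
#'
#' Maps compositions `(p1, p2, p3)` of gray levels 1, 2 and 3 to nominal
#' mosaic class codes. Compositions that do not sum to 1 (the window
#' contains other gray levels) are missing (`NA`).
#'
#' @param p1,p2,p3 numeric vectors of proportions
#' @param variant 19 (coarse partition) or 103 (fine partition)
#' @return numeric vector of class codes in `[1, 19]` or `[1, 103]`, `NA`
#'   where undefined. See [gsc_mosaic_legend()] for code meanings.
#' @examples
#' gsc_classify_mosaic(1, 0, 0)                 # pure class-1 corner
#' gsc_classify_mosaic(0.8, 0.1, 0.1)           # class 1 dominant, 2 and 3 present
#' gsc_classify_mosaic(0.5, 0.5, 0.3)           # NA: not a composition
#' @export
gsc_classify_mosaic <- function(p1, p2, p3, variant = 19L) {
  variant <- as.integer(variant)
  if (!variant %in% c(19L, 103L)) stop("`variant` must be 19 or 103")
  n <- max(length(p1), length(p2), length(p3))
  p1 <- rep_len(p1, n); p2 <- rep_len(p2, n); p3 <- rep_len(p3, n)
  vapply(seq_len(n), function(q)
    gsc_classify_mosaic1(p1[q], p2[q], p3[q], variant), numeric(1L))
}

#' Legend for the mosaic class codes
#'
#' @param variant 19 or 103
#' @return data.frame with `code`, `label` and `description`. In the
#'   19-class labels, the axes are lettered A/B/C for gray levels 1/2/3; an
#'   uppercase letter marks a dominant axis (>= 60%), lowercase a present
#'   axis (>= 10%), and doubled uppercase a pure corner (100%).
#' @export
gsc_mosaic_legend <- function(variant = 19L) {
  variant <- as.integer(variant)
  if (!variant %in% c(19L, 103L)) stop("`variant` must be 19 or 103")
  ax <- c("A", "B", "C")
  out <- data.frame(code = integer(), label = character(),
                    description = character(), stringsAsFactors = FALSE)
  add <- function(code, label, desc)
    out <<- rbind(out, data.frame(code = code, label = label,
                                  description = desc, stringsAsFactors = FALSE))
  for (d in 1:3)
    add(d, paste0(ax[d], ax[d]),
        sprintf("pure: p%d = 100%%", d))
  if (variant == 19L) {
    for (d in 1:3) {
      others <- setdiff(1:3, d)
      subs <- list(integer(0), others[1L], others[2L], others)
      for (w in 1:4) {
        lab <- paste0(ax[d], paste(tolower(ax[subs[[w]]]), collapse = ""))
        desc <- sprintf("p%d >= 60%%%s", d,
                        if (length(subs[[w]]))
                          paste0("; present (>=10%): ",
                                 paste0("p", subs[[w]], collapse = ", "))
                        else "; others < 10%")
        add(3L + (d - 1L) * 4L + w, lab, desc)
      }
    }
    combos <- list(1:2, c(1L, 3L), 2:3, 1:3)
    for (w in 1:4)
      add(15L + w, paste(tolower(ax[combos[[w]]]), collapse = ""),
          sprintf("no dominant axis; present (>=10%%): %s",
                  paste0("p", combos[[w]], collapse = ", ")))
  } else {
    t <- .gsc_m103
    for (i in 0:9) for (j in 0:(9 - i))
      add(t$up[i + 1L, j + 1L], sprintf("u%d.%d.%d", i, j, 9L - i - j),
          sprintf("upward cell: p1 in [%d0%%,%d0%%], p2 in [%d0%%,%d0%%], p3 in [%d0%%,%d0%%]",
                  i, i + 1L, j, j + 1L, 9L - i - j, 10L - i - j))
    for (i in 0:8) for (j in 0:(8 - i))
      add(t$down[i + 1L, j + 1L], sprintf("d%d.%d.%d", i, j, 8L - i - j),
          sprintf("downward cell: p1 in [%d0%%,%d0%%], p2 in [%d0%%,%d0%%], p3 in [%d0%%,%d0%%]",
                  i, i + 1L, j, j + 1L, 8L - i - j, 9L - i - j))
  }
  out
}

#' Write a mosaic legend text file
#'
#' Emitted alongside any mosaic metric map so class codes in the output
#' raster can be decoded.
#'
#' @param path file to write
#' @param variant 19 or 103
#' @return the path, invisibly
#' @export
gsc_write_mosaic_legend <- function(path, variant = 19L) {
  leg <- gsc_mosaic_legend(variant)
  lines <- c(sprintf("landscape mosaic legend (%d classes)", variant),
             "code\tlabel\tdescription",
             sprintf("%d\t%s\t%s", leg$code, leg$label, leg$description))
  writeLines(lines, path)
  invisible(path)
}
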