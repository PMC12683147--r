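# In-code fixtures shared across test files.

make_sheet <- function(...) {
  pts <- list(...)
  m <- do.call(rbind, pts)
  colnames(m) <- c("x", "y")
  rownames(m) <- names(pts)
  m
}

# complete random panel: m raters place the same n products at iid uniform
# positions (no latent structure)
random_panel <- function(n = 5, m = 3, seed = 1) {
  set.seed(seed)
  products <- sprintf("P%02d", seq_len(n))
  raters <- sprintf("R%02d", seq_len(m))
  sheets <- lapply(raters, function(r) {
    s <- matrix(runif(2 * n, 0, 30), n, 2, dimnames = list(products, c("x", "y")))
    s
  })
  names(sheets) <- raters
  napping_dataset(products, raters, sheets)
}

# apply a similarity transform to a sheet: rotation theta, optional
# reflection, translation, scale
transform_sheet <- function(sheet, theta = 0, reflect = FALSE,
                            translate = c(0, 0), scale = 1) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  if (reflect) R <- R %*% diag(c(1, -1))
  out <- scale * (sheet %*% R)
  out <- sweep(out, 2, translate, `+`)
  colnames(out) <- c("x", "y")
  out
}

write_tiny_napping_csv <- function(path, descriptors = TRUE) {
  lines <- c(
    if (descriptors) "rater,product,x,y,descriptors"
    else "rater,product,x,y",
    paste0("r1,P1,0,0", if (descriptors) ",\" Sweet; umami \"" else ""),
    paste0("r1,P2,3,4", if (descriptors) ",stable-like" else ""),
    paste0("r1,P3,10,0", if (descriptors) "," else ""),
    paste0("r2,P1,1,1", if (descriptors) ",sweet" else ""),
    paste0("r2,P2,5,1", if (descriptors) ",\"sour, metallic\"" else ""),
    paste0("r2,P3,1,9", if (descriptors) "," else ""))
  writeLines(lines, path)
  path
}

write_tiny_metadata_csv <- function(path) {
  writeLines(c("product,breed", "P1,STD", "P2,BIE", "P3,RAM"), path)
  path
}

# the paper-style worked example inputs: cluster labels and breed/feeding map
worked_example_labels <- function() {
  c(P01 = 1, P02 = 2, P03 = 2, P04 = 2, P05 = 3,
    P06 = 1, P07 = 2, P08 = 2, P09 = 2, P10 = 4)
}

worked_example_factors <- function() {
  c(P01 = "STD", P02 = "BIExWR_NOR", P03 = "RAMxWR_NOR", P04 = "BIExWR_ALF",
    P05 = "RAMxWR_ALF", P06 = "STD", P07 = "BIExWR_NOR", P08 = "RAMxWR_NOR",
    P09 = "BIExWR_ALF", P10 = "RAMxWR_ALF")
}

# small QDA dataset where panel averaging is the identity (single rater):
# two groups of 3 servings with scores {1,2,3} and {4,5,6}
two_group_qda <- function() {
  rec <- data.frame(
    rater = "r1",
    product = rep(c("A1", "A2", "A3", "B1", "B2", "B3")),
    serving = rep(c("A1", "A2", "A3", "B1", "B2", "B3")),
    attribute = "attr",
    score = c(1, 2, 3, 4, 5, 6))
  fac <- data.frame(group = rep(c("A", "B"), each = 3),
                    row.names = c("A1", "A2", "A3", "B1", "B2", "B3"))
  qda_dataset(rec, factors = fac, scale_max = 15)
}
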