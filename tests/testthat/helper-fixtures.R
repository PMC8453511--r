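# shared fixture builders (all data generated in code)

# a small hand-specified stand: heights/attributes chosen for easy sums
toy_trees <- function() {
  data.frame(
    x = c(1, 7, 12, 21, 33, 38),
    y = c(1, 8, 3, 6, 2, 9),
    dbh = c(2, 4, 6, 8, 10, 12),
    height = c(3, 5, 8, 12, 16, 20),
    crown_base = c(1, 2, 4, 6, 9, 11),
    crown_d1 = c(1, 1.5, 2, 2.5, 3, 4),
    crown_d2 = c(1, 1, 2, 2, 3, 3))
}

toy_inventory <- function(age = 15, plot_id = "T01") {
  stand_inventory(toy_trees(), plot_id, age)
}

# noiseless logistic light grid: every subplot follows the same curve
noiseless_grid <- function(a, b, heights = 1:22, n_subplots = 16,
                           plot_id = "G01", age = 10) {
  y <- 100 / (1 + exp(-a * (heights - b)))
  light_grid(matrix(rep(y, each = n_subplots), n_subplots),
             heights, plot_id, age)
}

# random valid stand for property tests
random_inventory <- function(n = 50, age = 20, plot_id = "R01") {
  h <- runif(n, 2, 25)
  cb <- h * runif(n, 0.2, 0.8)
  stand_inventory(
    data.frame(x = runif(n, 0, 40), y = runif(n, 0, 10),
               dbh = runif(n, 1.5, 30), height = h, crown_base = cb,
               crown_d1 = runif(n, 0.5, 6), crown_d2 = runif(n, 0.5, 6)),
    plot_id, age)
}
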