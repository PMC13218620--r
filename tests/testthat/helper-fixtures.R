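# Shared fixtures, built once per test run. Everything is generated in
# code (no stored data) under fixed seeds.

GLUTATHIONE <- "C(CC(=O)NC(CS)C(=O)NCC(=O)O)C(C(=O)O)N"
ESTRONE <- "CC12CCC3c4ccc(O)cc4CCC3C1CCC2=O"
MELATONIN <- "CC(=O)NCCc1c[nH]c2ccc(OC)cc12"
METHOTREXATE <- "CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(C(=O)NC(CCC(=O)O)C(=O)O)cc1"

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small planted-SAR set + features, reused across test files
small_set <- function() fixture("small_set", function() {
  spec <- synthetic_spec(n_ligands = 100L, seed = 42L)
  lig <- generate_ligand_set(spec)
  fe <- featurize_table(lig$table)
  lab <- classify_activity(lig$table$pic50)
  list(spec = spec, lig = lig, fe = fe, lab = lab,
       X = build_feature_matrix(lig$table, features = fe))
})

# the full-scale default set (study conditions); built on first use
big_set <- function() fixture("big_set", function() {
  spec <- synthetic_spec(seed = 1L)     # defaults: n = 2000, sigma = 0.4
  lig <- generate_ligand_set(spec)
  list(spec = spec, lig = lig)
})

# a trained fusion model on the small set
small_fusion <- function() fixture("small_fusion", function() {
  s <- small_set()
  pairs <- build_pair_dataset(s$lig$table, s$lab, max_pairs = 400L, seed = 1L)
  cfg <- fusion_config(hidden_dim = 64L, n_heads = 4L, mlp_dims = c(64L, 16L),
                       max_epochs = 25L, batch_size = 32L, seed = 1L)
  model <- train_fusion(chemfusion_init(s$fe, cfg), s$fe, pairs)
  list(model = model, pairs = pairs)
})

write_temp_csv <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
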