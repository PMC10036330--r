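# triadsync

Do three-body interactions help or hinder synchronization? The answer turns
out to depend on how they are represented. **triadsync** is an R package for
analyzing the linear stability of full synchronization in networks of
identical phase oscillators coupled through both pairwise links and triadic
(three-body) interactions, and for explaining the stability through the
degree structure of the underlying hypergraph.

Its central result, reproducible from the package's generators alone: moving
coupling strength from pairwise to triadic interactions *destabilizes*
synchrony on simplicial complexes (2-simplices attached to the closed
triangles of a graph), but *stabilizes* it on random hypergraphs — and the
mechanism is degree heterogeneity amplified (or suppressed) at the triadic
order, modulated by the correlation between pairwise and triadic degrees.

## The model

`n` identical oscillators with phases `θ_i` evolve as

    dθ_i/dt = ω + (1-α)/⟨k⁽¹⁾⟩ Σ_j A_ij sin(θ_j - θ_i)
                +   α/⟨k⁽²⁾⟩ Σ_{2-simplices {i,j,k}} ½ sin(θ_j + θ_k - 2θ_i)

where `A` is the pairwise adjacency matrix, the triadic sum runs over the
2-simplices containing `i`, and `α ∈ [0,1]` shifts a fixed total coupling
budget from purely pairwise (`α = 0`) to purely triadic (`α = 1`). Each
order is normalized by its mean generalized degree `⟨k⁽ℓ⁾⟩`.

Linearizing around full synchrony gives `d(δθ)/dt = -L(mul) δθ` with the
**multiorder Laplacian**

    L(mul) = (1-α)/⟨k⁽¹⁾⟩ L⁽¹⁾ + α/⟨k⁽²⁾⟩ L⁽²⁾,
    L⁽¹⁾ = diag(k⁽¹⁾) - A,   L⁽²⁾ = diag(k⁽²⁾) - A⁽²⁾/2,

where `A⁽²⁾_ij` counts the 2-simplices containing both `i` and `j`. Sorting
the eigenvalues `0 = Λ_n ≤ … ≤ Λ_1`, the **second Lyapunov exponent**
`λ₂ = -Λ_{n-1}` measures stability: `λ₂ < 0` is stable synchrony, larger
magnitude means faster recovery. `λ₂` is bracketed by the extreme multiorder
degrees (`2k_min - n + 2 ≤ |λ₂| ≤ n/(n-1) k_min`), which links stability to
degree heterogeneity: in flag complexes of Erdős–Rényi graphs
`E[k⁽²⁾|k⁽¹⁾] = p·k⁽¹⁾(k⁽¹⁾-1)/2` (rich get richer, heterogeneity ratio
`r = (k⁽²⁾_max/k⁽²⁾_min)/(k⁽¹⁾_max/k⁽¹⁾_min) > 1`), while in random
hypergraphs Gumbel extreme-value estimates give heterogeneity indexes with
`h⁽¹⁾/h⁽²⁾ ≳ √n/2 ≫ 1`.

## Worked example

```r
library(triadsync)

# a random hypergraph: pairs and triples wired independently
H <- random_hypergraph(100, p = 0.1, p_tri = 0.1, seed = 1)
H
#> hypergraph: 100 nodes, 514 edges, 16069 triangles (not simplicial)
lambda2(H, 0)$lambda2    #> -0.290020
lambda2(H, 1)$lambda2    #> -0.904914
hetero_report(H)
#> heterogeneity report: r = 0.2717, DC = -0.04373, <k1> = 10.280, <k2> = 482.070

# a simplicial complex: flag complex of an ER graph
S <- flag_complex(er_graph(100, 0.5, seed = 1))
S
#> hypergraph: 100 nodes, 2478 edges, 19978 triangles (simplicial complex)
lambda2(S, 0)$lambda2    #> -0.780058
lambda2(S, 1)$lambda2    #> -0.696759
hetero_report(S)
#> heterogeneity report: r = 1.484, DC = 0.9901, <k1> = 49.560, <k2> = 599.340
```

Reading the numbers: on the random hypergraph, shifting coupling to the
triadic order deepens `λ₂` from −0.29 to −0.90 (triadic degrees are far more
homogeneous: `r ≈ 0.27 < 1`, cross-order degree correlation `DC ≈ 0`), so
higher-order interactions *promote* synchronization. On the simplicial
complex the trend reverses (−0.78 to −0.70) because the inclusion condition
makes triadic degrees *more* heterogeneous (`r ≈ 1.5 > 1`) and strongly
correlated with pairwise degrees (`DC ≈ 0.99`).

Ensemble versions of these analyses, the U-shaped `λ₂(α)` curves, the
simplex-shuffling transition and the degree-preserving membership-swap
experiment are driven by `alpha_sweep()`, `shuffle_transition()`,
`swap_memberships()` and `run_experiment()`; see the vignette in
`vignettes/multiorder-stability.Rmd`.

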