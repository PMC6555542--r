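"""Coalescent simulation driver for the archtrace R package.

Simulates replicate regions under a three-population split/admixture
demography (ancestral -> archaic + modern; modern -> reference + target;
single-generation archaic admixture pulse into the target) and records,
for every target haplotype, the base-pair intervals that descend from the
archaic population.  Ancestry tracts are obtained by placing a census on
every lineage just after the admixture pulse (backwards in time) and
mapping each sampled segment to the population of its census ancestor.

Input: a JSON config file (written by the R wrapper).  Output: an ms-style
haplotype file (optional) and a BED-like tract table.  All randomness is
derived from the single 'seed' entry via numpy.random.SeedSequence, so a
(seed, replicate-index) pair always maps to the same data.
"""

import json
import sys

import msprime
import numpy as np


def build_demography(sc):
    d = msprime.Demography()
    d.add_population(name="target", initial_size=sc["N2"])
    d.add_population(name="ref1", initial_size=sc["N1"])
    d.add_population(name="arch", initial_size=sc["Na"])
    d.add_population(name="mh", initial_size=sc["N0"])
    d.add_population(name="anc", initial_size=sc["N0"])

    structure = sc.get("structure") or []
    host_size = {"target": sc["N2"], "ancestral": sc["N0"]}
    for i, ev in enumerate(structure):
        d.add_population(
            name="struct%d" % i,
            initial_size=ev["fraction"] * host_size[ev["population"]],
        )

    m = sc["m"]
    if m > 0:
        # Backwards in time: at Ta each target lineage moves to the archaic
        # population with probability m (a single-generation pulse).
        d.add_mass_migration(time=sc["Ta"], source="target", dest="arch", proportion=m)
        # Census between the pulse and the target/reference split: a target
        # lineage sitting in 'arch' here carries archaic ancestry.
        d.add_census(time=sc["Ta"] + 0.5)

    d.add_population_split(time=sc["Ts"], derived=["target", "ref1"], ancestral="mh")
    d.add_population_split(time=sc["T0"], derived=["mh", "arch"], ancestral="anc")

    # Structure-event migrations are added after the splits so that, at a
    # tied event time (e.g. a deme absorbed exactly at T0), the stable
    # event sort runs the split first and the sink population is active.
    for i, ev in enumerate(structure):
        name = "struct%d" % i
        host = "target" if ev["population"] == "target" else "mh"
        # Forwards in time the deme splits at split_time and rejoins at
        # rejoin_time; backwards, lineages enter the deme at rejoin_time and
        # leave it at split_time.  Full isolation in between.
        d.add_mass_migration(
            time=ev["rejoin_time"], source=host, dest=name, proportion=ev["fraction"]
        )
        sink = host
        if ev["population"] == "target" and ev["split_time"] >= sc["Ts"]:
            sink = "mh"
        if ev["population"] == "ancestral" and ev["split_time"] >= sc["T0"]:
            sink = "anc"
        d.add_mass_migration(
            time=ev["split_time"], source=name, dest=sink, proportion=1.0
        )

    d.sort_events()
    return d


def integer_positions(raw, length):
    """Map continuous infinite-sites positions to strictly increasing
    integer bp; colliding positions are bumped to the next free integer."""
    out = []
    prev = -1
    for x in raw:
        p = int(x)
        if p <= prev:
            p = prev + 1
        if p >= length:
            p = -1  # dropped (can only happen in a full terminal run)
        out.append(p)
        prev = p if p >= 0 else prev
    return out


def archaic_tracts(ts, n_target, arch_id):
    """Per-target-haplotype archaic intervals, merged and sorted."""
    tab = ts.tables
    census = np.where(tab.nodes.flags & msprime.NODE_IS_CEN_EVENT)[0].astype(np.int32)
    if len(census) == 0:
        return {}
    links = tab.link_ancestors(
        samples=np.arange(n_target, dtype=np.int32), ancestors=census
    )
    pops = tab.nodes.population
    keep = pops[links.parent] == arch_id
    tracts = {}
    for left, right, child in zip(
        links.left[keep], links.right[keep], links.child[keep]
    ):
        tracts.setdefault(int(child), []).append((float(left), float(right)))
    merged = {}
    for child, iv in tracts.items():
        iv.sort()
        out = [list(iv[0])]
        for a, b in iv[1:]:
            if a <= out[-1][1]:
                out[-1][1] = max(out[-1][1], b)
            else:
                out.append([a, b])
        merged[child] = [(int(a), int(b)) for a, b in out]
    return merged


def main(cfg_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)

    sc = cfg["scenario"]
    n_target = int(cfg["n_target"])
    n_ref = int(cfg["n_ref"])
    n_arch = int(cfg["n_archaic"])
    n_rep = int(cfg["n_rep"])
    length = int(sc["length_bp"])
    tracts_only = bool(cfg.get("tracts_only", False))
    mu_list = cfg.get("mu_list")  # optional per-replicate rates
    r_list = cfg.get("r_list")

    dem = build_demography(sc)
    arch_id = next(p.id for p in dem.populations if p.name == "arch")

    ss = np.random.SeedSequence(int(cfg["seed"]))
    rep_seeds = [
        child.generate_state(2) % (2**31 - 2) + 1 for child in ss.spawn(n_rep)
    ]

    samples = []
    if n_target > 0:
        samples.append(msprime.SampleSet(n_target, population="target", ploidy=1))
    if n_ref > 0:
        samples.append(msprime.SampleSet(n_ref, population="ref1", ploidy=1))
    if n_arch > 0:
        samples.append(msprime.SampleSet(n_arch, population="arch", ploidy=1))
    nsam = n_target + n_ref + n_arch

    ms_fh = open(cfg["out_ms"], "w") if not tracts_only else None
    tr_fh = open(cfg["out_tracts"], "w")
    tr_fh.write("rep\thap\tstart\tend\n")
    if ms_fh:
        ms_fh.write("ms %d %d (archtrace msprime driver)\n%d\n" % (nsam, n_rep, cfg["seed"]))

    for rep in range(n_rep):
        s_anc, s_mut = (int(rep_seeds[rep][0]), int(rep_seeds[rep][1]))
        rr = r_list[rep] if r_list else sc["r"]
        mu = mu_list[rep] if mu_list else sc["mu"]
        ts = msprime.sim_ancestry(
            samples=samples,
            demography=dem,
            sequence_length=length,
            recombination_rate=rr,
            ploidy=2,
            random_seed=s_anc,
        )
        tracts = archaic_tracts(ts, n_target, arch_id) if n_target > 0 else {}
        for hap in sorted(tracts):
            for a, b in tracts[hap]:
                # hap written 1-based (R panel index), coords 0-based half-open
                tr_fh.write("%d\t%d\t%d\t%d\n" % (rep + 1, hap + 1, a, b))

        if ms_fh:
            mts = msprime.sim_mutations(
                ts,
                rate=mu,
                model=msprime.BinaryMutationModel(),
                discrete_genome=False,
                random_seed=s_mut,
            )
            pos = integer_positions([site.position for site in mts.sites()], length)
            keep = [i for i, p in enumerate(pos) if p >= 0]
            G = mts.genotype_matrix()  # sites x samples, 0/1
            ms_fh.write("\n//\nsegsites: %d\n" % len(keep))
            if keep:
                ms_fh.write(
                    "positions: "
                    + " ".join("%.10f" % (pos[i] / length) for i in keep)
                    + "\n"
                )
                Gk = G[keep, :]
                for j in range(nsam):
                    ms_fh.write("".join("1" if g else "0" for g in Gk[:, j]) + "\n")

    tr_fh.close()
    if ms_fh:
        ms_fh.close()
    sys.stdout.write("OK %d\n" % n_rep)


if __name__ == "__main__":
    main(sys.argv[1])
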