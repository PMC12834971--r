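"""JSON-lines chemistry worker.

Reads one JSON request per line on stdin, writes one JSON response per line
on stdout.  Serves RDKit primitives (validity/canonical SMILES, QED, SA
score, Morgan fingerprints, substructure matching, kekulisation) and a
scikit-learn t-SNE embedding.  Kept as a long-lived process so the RDKit
import cost is paid once per R session.
"""
import json
import sys


def _lazy_rdkit():
    global Chem, QED, sascorer, rdFingerprintGenerator
    from rdkit import Chem, RDConfig
    from rdkit.Chem import QED, rdFingerprintGenerator
    from rdkit import RDLogger
    RDLogger.DisableLog("rdApp.*")
    import os
    sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
    import sascorer
    return None


_rdkit_ready = False


def need_rdkit():
    global _rdkit_ready
    if not _rdkit_ready:
        _lazy_rdkit()
        _rdkit_ready = True


def mols_from(smiles):
    need_rdkit()
    return [Chem.MolFromSmiles(s) if isinstance(s, str) else None for s in smiles]


def op_ping(req):
    return {"pong": True}


def op_valid(req):
    mols = mols_from(req["smiles"])
    return {"valid": [m is not None for m in mols],
            "canonical": [Chem.MolToSmiles(m) if m is not None else None
                          for m in mols]}


def op_props(req):
    mols = mols_from(req["smiles"])
    qed, sa = [], []
    for m in mols:
        if m is None:
            qed.append(None)
            sa.append(None)
        else:
            qed.append(QED.qed(m))
            sa.append(sascorer.calculateScore(m))
    return {"qed": qed, "sa": sa}


def op_morgan(req):
    mols = mols_from(req["smiles"])
    radius = int(req.get("radius", 2))
    nbits = int(req.get("nbits", 2048))
    gen = rdFingerprintGenerator.GetMorganGenerator(radius=radius, fpSize=nbits)
    out = []
    for m in mols:
        if m is None:
            out.append(None)
        else:
            fp = gen.GetFingerprint(m)
            out.append(list(fp.GetOnBits()))
    return {"bits": out, "nbits": nbits}


def op_substruct(req):
    mols = mols_from(req["smiles"])
    patt = Chem.MolFromSmiles(req["pattern"])
    if patt is None:
        patt = Chem.MolFromSmarts(req["pattern"])
    if patt is None:
        return {"error": "unparseable pattern: %s" % req["pattern"]}
    return {"match": [m.HasSubstructMatch(patt) if m is not None else None
                      for m in mols]}


def op_kekulize(req):
    mols = mols_from(req["smiles"])
    out = []
    for m in mols:
        if m is None:
            out.append(None)
        else:
            out.append(Chem.MolToSmiles(m, kekuleSmiles=True))
    return {"smiles": out}


def op_tsne(req):
    import numpy as np
    from sklearn.manifold import TSNE
    nbits = int(req["nbits"])
    rows = req["bits"]
    x = np.zeros((len(rows), nbits))
    for i, r in enumerate(rows):
        if r:
            x[i, np.asarray(r, dtype=int)] = 1.0
    emb = TSNE(n_components=2, perplexity=float(req["perplexity"]),
               random_state=int(req["seed"]), init="pca").fit_transform(x)
    return {"xy": emb.tolist()}


OPS = {"ping": op_ping, "valid": op_valid, "props": op_props,
       "morgan": op_morgan, "substruct": op_substruct,
       "kekulize": op_kekulize, "tsne": op_tsne}


def main():
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        try:
            req = json.loads(line)
            if req.get("op") == "quit":
                break
            res = OPS[req["op"]](req)
        except Exception as exc:  # report, never die
            res = {"error": "%s: %s" % (type(exc).__name__, exc)}
        sys.stdout.write(json.dumps(res) + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    main()
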