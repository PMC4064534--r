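# Built-in PROSITE-syntax catalogue of PTM-site and sequence-motif consensus
# patterns.  One pattern per line: name<TAB>pattern<TAB>kind, where kind is
# "count" (discrete number of sites) or "binary" (presence/absence).
# The catalogue is user-editable; lines starting with '#' are comments.
#
# PS00001 N-glycosylation site consensus
ASN_GLYCOSYLATION	N-{P}-[ST]-{P}	count
# PS00002 glycosaminoglycan attachment site
GLYCOSAMINOGLYCAN	S-G-x-G	count
# PS00004 cAMP/cGMP-dependent protein kinase phosphorylation site
CAMP_PHOSPHO_SITE	[RK](2)-x-[ST]	count
# PS00005 protein kinase C phosphorylation site
PKC_PHOSPHO_SITE	[ST]-x-[RK]	count
# PS00006 casein kinase II phosphorylation site
CK2_PHOSPHO_SITE	[ST]-x(2)-[DE]	count
# PS00007 tyrosine kinase phosphorylation site
TYR_PHOSPHO_SITE	[RK]-x(2,3)-[DE]-x(2,3)-Y	count
# PS00008 N-myristoylation site
MYRISTYL	G-{EDRKHPFYW}-x(2)-[STAGCN]-{P}	count
# PS00009 amidation site
AMIDATION	x-G-[RK]-[RK]	count
# PS00010 aspartate/asparagine hydroxylation site (EGF-domain context)
ASX_HYDROXYL	C-x-[DN]-x(4)-[FY]-x-C-x-C	count
# acidic-context tyrosine sulfation consensus (simplified synthetic consensus)
TYR_SULFATION	[DE]-x(0,1)-Y-x(0,1)-[DE]	count
# C-terminal CAAX-type prenylation box (aliphatic consensus)
PRENYLATION_CAAX	C-[LIVMAF]-[LIVMAF]-x>	binary
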