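surface,canonical_id,canonical_name
lactose monohydrate,lactose_monohydrate,Lactose monohydrate
lactose,lactose_monohydrate,Lactose monohydrate
anhydrous lactose,lactose_anhydrous,Anhydrous lactose
lactose anhydrous,lactose_anhydrous,Anhydrous lactose
microcrystalline cellulose,microcrystalline_cellulose,Microcrystalline cellulose
cellulose microcrystalline,microcrystalline_cellulose,Microcrystalline cellulose
cellulose powdered,powdered_cellulose,Powdered cellulose
macrogol,macrogol,Macrogol
macrogol 400,macrogol,Macrogol
macrogol 3350,macrogol,Macrogol
macrogol 4000,macrogol,Macrogol
macrogol 6000,macrogol,Macrogol
macrogol 8000,macrogol,Macrogol
polyethylene glycol,macrogol,Macrogol
polyethylene glycol 400,macrogol,Macrogol
polyethylene glycol 4000,macrogol,Macrogol
polyethylene glycol 6000,macrogol,Macrogol
peg 400,macrogol,Macrogol
peg 6000,macrogol,Macrogol
povidone,povidone,Povidone
povidone k25,povidone,Povidone
povidone k29/32,povidone,Povidone
povidone k30,povidone,Povidone
povidone k90,povidone,Povidone
polyvidone,povidone,Povidone
polyvinylpyrrolidone,povidone,Povidone
copovidone,copovidone,Copovidone
copolyvidone,copovidone,Copovidone
crospovidone,crospovidone,Crospovidone
crospovidone type a,crospovidone,Crospovidone
crospovidone type b,crospovidone,Crospovidone
hypromellose,hypromellose,Hypromellose
hypromellose 2910,hypromellose,Hypromellose
hypromellose 2208,hypromellose,Hypromellose
hydroxypropyl methylcellulose,hypromellose,Hypromellose
hpmc,hypromellose,Hypromellose
hypromellose acetate succinate,hypromellose_acetate_succinate,Hypromellose acetate succinate
hpmc-as,hypromellose_acetate_succinate,Hypromellose acetate succinate
hypromellose phthalate,hypromellose_phthalate,Hypromellose phthalate
hydroxypropyl cellulose,hydroxypropyl_cellulose,Hydroxypropyl cellulose
hydroxypropylcellulose,hydroxypropyl_cellulose,Hydroxypropyl cellulose
low-substituted hydroxypropyl cellulose,hydroxypropyl_cellulose_low_substituted,Low-substituted hydroxypropyl cellulose
ethylcellulose,ethylcellulose,Ethylcellulose
ethyl cellulose,ethylcellulose,Ethylcellulose
methylcellulose,methylcellulose,Methylcellulose
croscarmellose sodium,croscarmellose_sodium,Croscarmellose sodium
carmellose sodium,carmellose_sodium,Carmellose sodium
carboxymethylcellulose sodium,carmellose_sodium,Carmellose sodium
sodium starch glycolate,sodium_starch_glycolate,Sodium starch glycolate
sodium starch glycolate type a,sodium_starch_glycolate,Sodium starch glycolate
maize starch,maize_starch,Maize starch
corn starch,maize_starch,Maize starch
pregelatinised starch,pregelatinised_starch,Pregelatinised starch
pregelatinized starch,pregelatinised_starch,Pregelatinised starch
potato starch,potato_starch,Potato starch
magnesium stearate,magnesium_stearate,Magnesium stearate
stearic acid,stearic_acid,Stearic acid
calcium stearate,calcium_stearate,Calcium stearate
sodium stearyl fumarate,sodium_stearyl_fumarate,Sodium stearyl fumarate
glyceryl behenate,glyceryl_behenate,Glyceryl behenate
glyceryl monostearate,glyceryl_monostearate,Glyceryl monostearate
colloidal anhydrous silica,colloidal_silica,Colloidal anhydrous silica
silica colloidal anhydrous,colloidal_silica,Colloidal anhydrous silica
colloidal silicon dioxide,colloidal_silica,Colloidal anhydrous silica
silicon dioxide,colloidal_silica,Colloidal anhydrous silica
talc,talc,Talc
titanium dioxide,titanium_dioxide,Titanium dioxide
titanium dioxide (e171),titanium_dioxide,Titanium dioxide
iron oxide red,iron_oxide_red,Iron oxide red
red iron oxide,iron_oxide_red,Iron oxide red
iron oxide red (e172),iron_oxide_red,Iron oxide red
iron oxide yellow,iron_oxide_yellow,Iron oxide yellow
iron oxide yellow (e172),iron_oxide_yellow,Iron oxide yellow
iron oxide black,iron_oxide_black,Iron oxide black
mannitol,mannitol,Mannitol
sorbitol,sorbitol,Sorbitol
xylitol,xylitol,Xylitol
sucrose,sucrose,Sucrose
glucose,glucose,Glucose
calcium hydrogen phosphate,calcium_hydrogen_phosphate,Calcium hydrogen phosphate
calcium hydrogen phosphate dihydrate,calcium_hydrogen_phosphate,Calcium hydrogen phosphate
dibasic calcium phosphate,calcium_hydrogen_phosphate,Calcium hydrogen phosphate
calcium carbonate,calcium_carbonate,Calcium carbonate
sodium hydrogen carbonate,sodium_hydrogen_carbonate,Sodium hydrogen carbonate
sodium bicarbonate,sodium_hydrogen_carbonate,Sodium hydrogen carbonate
sodium lauryl sulfate,sodium_lauryl_sulfate,Sodium lauryl sulfate
sodium laurilsulfate,sodium_lauryl_sulfate,Sodium lauryl sulfate
sodium lauryl sulphate,sodium_lauryl_sulfate,Sodium lauryl sulfate
polysorbate 20,polysorbate_20,Polysorbate 20
tween 20,polysorbate_20,Polysorbate 20
polysorbate 80,polysorbate_80,Polysorbate 80
tween 80,polysorbate_80,Polysorbate 80
sorbitan monolaurate,sorbitan_monolaurate,Sorbitan monolaurate
sorbitan laurate,sorbitan_monolaurate,Sorbitan monolaurate
span 20,sorbitan_monolaurate,Sorbitan monolaurate
poloxamer,poloxamer,Poloxamer
poloxamer 188,poloxamer,Poloxamer
poloxamer 407,poloxamer,Poloxamer
gelatin,gelatin,Gelatin
glycerol,glycerol,Glycerol
glycerin,glycerol,Glycerol
propylene glycol,propylene_glycol,Propylene glycol
triethyl citrate,triethyl_citrate,Triethyl citrate
triacetin,triacetin,Triacetin
dibutyl sebacate,dibutyl_sebacate,Dibutyl sebacate
citric acid,citric_acid,Citric acid
citric acid monohydrate,citric_acid,Citric acid
tartaric acid,tartaric_acid,Tartaric acid
fumaric acid,fumaric_acid,Fumaric acid
sodium citrate,sodium_citrate,Sodium citrate
disodium edetate,disodium_edetate,Disodium edetate
edetate disodium,disodium_edetate,Disodium edetate
butylhydroxytoluene,butylhydroxytoluene,Butylhydroxytoluene
butylated hydroxytoluene,butylhydroxytoluene,Butylhydroxytoluene
butylhydroxyanisole,butylhydroxyanisole,Butylhydroxyanisole
methacrylic acid - ethyl acrylate copolymer,methacrylic_acid_copolymer,Methacrylic acid copolymer
methacrylic acid - methyl methacrylate copolymer,methacrylic_acid_copolymer,Methacrylic acid copolymer
eudragit l30d-55,methacrylic_acid_copolymer,Methacrylic acid copolymer
basic butylated methacrylate copolymer,basic_methacrylate_copolymer,Basic butylated methacrylate copolymer
shellac,shellac,Shellac
carnauba wax,carnauba_wax,Carnauba wax
hard fat,hard_fat,Hard fat
macrogol stearate,macrogol_stearate,Macrogol stearate
macrogol 40 stearate,macrogol_stearate,Macrogol stearate
sodium chloride,sodium_chloride,Sodium chloride
potassium chloride,potassium_chloride,Potassium chloride
magnesium oxide,magnesium_oxide,Magnesium oxide
meglumine,meglumine,Meglumine
urea,urea,Urea
vanillin,vanillin,Vanillin
saccharin sodium,saccharin_sodium,Saccharin sodium
aspartame,aspartame,Aspartame
sodium hydroxide,sodium_hydroxide,Sodium hydroxide
hydrochloric acid,hydrochloric_acid,Hydrochloric acid
water for injections,water_for_injections,Water for injections
water,water_for_injections,Water for injections
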